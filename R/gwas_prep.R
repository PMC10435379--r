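# GWAS preparation: representative-subset construction from box selection
# fractions, effective minor-allele-count filtering, case definition from
# diagnosis codes, a logistic association scan with Firth fallback,
# fixed-effect region-stratified meta-analysis, and LD clumping.

#' Population-representative subset from storage-box selection fractions
#'
#' Disease-case over-ascertainment concentrates in storage boxes that were
#' sampled sparsely for genotyping; restricting to samples whose source box
#' had a genotyping selection fraction at or above the threshold removes the
#' over-representation. The report compares ascertained-case prevalence
#' inside and outside the subset.
#'
#' @param manifest data.frame of genotyped samples with `sample_id`, `box`
#'   and optionally `ascertainment`
#' @param box_fractions data.frame with `box` and `fraction` (selected for
#'   genotyping / stored), or a named vector
#' @param threshold minimum selection fraction (default 0.40; the boundary
#'   is inclusive)
#' @return list with `subset_ids`, `excluded_ids`, `report` (per-disease
#'   prevalence inside/outside)
#' @export
representative_subset <- function(manifest, box_fractions, threshold = 0.40) {
  if (is.data.frame(box_fractions))
    box_fractions <- stats::setNames(box_fractions$fraction, box_fractions$box)
  fr <- box_fractions[as.character(manifest$box)]
  unmapped <- is.na(fr)
  if (any(unmapped))
    warning(sum(unmapped), " sample(s) with no source box mapping; excluded")
  inset <- !unmapped & fr >= threshold
  report <- NULL
  if ("ascertainment" %in% names(manifest)) {
    dis <- setdiff(unique(manifest$ascertainment), c("random", NA))
    if (length(dis)) {
      report <- do.call(rbind, lapply(dis, function(d) {
        data.frame(disease = d,
                   prev_inside = mean(manifest$ascertainment[inset] == d,
                                      na.rm = TRUE),
                   prev_outside = mean(manifest$ascertainment[!inset] == d,
                                       na.rm = TRUE))
      }))
    }
  }
  list(subset_ids = manifest$sample_id[inset],
       excluded_ids = manifest$sample_id[!inset],
       report = report)
}

#' Effective minor-allele-count filter
#'
#' MAC_eff = 2 * MAF * info * N_eff with N_eff = 4 / (1/N_cases +
#' 1/N_controls); variants with MAC_eff below the threshold are dropped.
#'
#' @param maf minor allele frequency (vector)
#' @param info imputation info score in \[0, 1\]; values above 1 are clamped
#'   with a warning
#' @param n_cases,n_controls case/control counts (must be positive)
#' @param threshold minimum effective MAC (default 20)
#' @return data.frame with `n_eff`, `mac_eff`, `keep`
#' @export
mac_eff_filter <- function(maf, info, n_cases, n_controls, threshold = 20) {
  if (any(n_cases <= 0) || any(n_controls <= 0))
    stop("n_cases and n_controls must be positive")
  if (any(maf < 0) || any(info < 0)) stop("maf and info must be non-negative")
  if (any(info > 1)) {
    warning("info scores above 1 clamped to 1")
    info <- pmin(info, 1)
  }
  n_eff <- 4 / (1 / n_cases + 1 / n_controls)
  mac_eff <- 2 * maf * info * n_eff
  data.frame(n_eff = n_eff, mac_eff = mac_eff, keep = mac_eff >= threshold)
}

#' Define case/control phenotypes from diagnosis codes
#'
#' One phenotype per 3-character diagnosis code with at least `min_cases`
#' genotyped cases; controls are the non-case members of the representative
#' subset. Sex-specific codes restrict both cases and controls to the
#' corresponding sex before the case-count check.
#'
#' @param events data.frame with `sample_id`, `code`
#' @param genotyped_ids ids of genotyped, QC-passing samples
#' @param subset_ids ids of the representative subset (control pool)
#' @param sex named per-sample sex vector (required if `sex_map` used)
#' @param sex_map named character vector code -> `"M"`/`"F"` for
#'   sex-specific diseases
#' @param min_cases minimum genotyped cases (default 100)
#' @return named list per retained code: list with `cases`, `controls`;
#'   skipped codes recorded in attribute `skipped`
#' @export
case_definition <- function(events, genotyped_ids, subset_ids, sex = NULL,
                            sex_map = NULL, min_cases = 100) {
  out <- list(); skipped <- character(0)
  for (cd in sort(unique(events$code))) {
    cases <- intersect(unique(events$sample_id[events$code == cd]),
                       genotyped_ids)
    controls <- setdiff(subset_ids, unique(events$sample_id[events$code == cd]))
    if (!is.null(sex_map) && cd %in% names(sex_map)) {
      if (is.null(sex)) stop("sex vector required for sex-specific codes")
      want <- sex_map[[cd]]
      cases <- cases[!is.na(sex[cases]) & sex[cases] == want]
      controls <- controls[!is.na(sex[controls]) & sex[controls] == want]
    }
    if (length(cases) < min_cases) {
      skipped <- c(skipped, cd)
      next
    }
    out[[cd]] <- list(cases = cases, controls = controls)
  }
  attr(out, "skipped") <- skipped
  out
}

# Firth-penalised logistic regression (Jeffreys prior) by Newton iteration;
# used as the fallback when plain ML separates or fails to converge
firth_logistic <- function(x, y, max_iter = 50, tol = 1e-6) {
  p <- ncol(x)
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    xw <- x * sqrt(w)
    info <- crossprod(xw)
    inv <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(inv)) return(NULL)
    h <- rowSums((x %*% inv) * x) * w          # hat diagonal
    u <- drop(t(x) %*% (y - mu + h * (0.5 - mu)))
    step <- drop(inv %*% u)
    beta <- beta + step
    if (max(abs(step)) < tol) {
      se <- sqrt(diag(inv))
      return(list(beta = beta, se = se, converged = TRUE))
    }
  }
  NULL
}

#' Per-variant logistic association scan
#'
#' Plain logistic regression of case status on genotype dosage with the
#' standard covariate recipe (array version, sex, age, age squared,
#' recruitment region indicators, leading PCs), falling back to
#' Firth-penalised regression on separation or non-convergence. This is a
#' desk-scale stand-in for a saddlepoint-corrected mixed-model scan and is
#' labelled as such in its output attribute.
#'
#' @param genotypes dosage matrix (samples x variants)
#' @param phenotype 0/1 case status
#' @param covariates data.frame or matrix of covariates (may be `NULL`)
#' @return data.frame per variant: `beta`, `se`, `p`, `n_cases`,
#'   `n_controls`, `flag` (`monomorphic`, `firth`, `nonconverged`)
#' @export
association_scan <- function(genotypes, phenotype, covariates = NULL) {
  y <- as.integer(phenotype)
  n <- length(y)
  cv <- if (is.null(covariates)) matrix(nrow = n, ncol = 0) else
    stats::model.matrix(~., data = as.data.frame(covariates))[, -1, drop = FALSE]
  x0 <- cbind(`(Intercept)` = 1, cv)
  qrx <- qr(x0)
  if (qrx$rank < ncol(x0)) stop("covariate matrix is rank deficient")
  m <- ncol(genotypes)
  out <- data.frame(beta = rep(NA_real_, m), se = NA_real_, p = NA_real_,
                    n_cases = NA_integer_, n_controls = NA_integer_,
                    flag = NA_character_)
  rownames(out) <- colnames(genotypes)
  for (j in seq_len(m)) {
    g <- genotypes[, j]
    ok <- !is.na(g)
    if (length(unique(g[ok])) < 2) { out$flag[j] <- "monomorphic"; next }
    xj <- cbind(x0[ok, , drop = FALSE], g = g[ok])
    yj <- y[ok]
    out$n_cases[j] <- sum(yj == 1); out$n_controls[j] <- sum(yj == 0)
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(xj, yj, family = stats::binomial())),
      error = function(e) NULL)
    use_firth <- is.null(fit) || !fit$converged ||
      abs(fit$coefficients["g"]) > 8
    if (!use_firth) {
      # Wald SE from the weighted information
      w <- fit$weights
      inv <- tryCatch(solve(crossprod(xj * sqrt(w))), error = function(e) NULL)
      if (is.null(inv) || inv["g", "g"] <= 0) use_firth <- TRUE
      else {
        out$beta[j] <- fit$coefficients["g"]
        out$se[j] <- sqrt(inv["g", "g"])
      }
    }
    if (use_firth) {
      ff <- firth_logistic(xj, yj)
      if (is.null(ff)) { out$flag[j] <- "nonconverged"; next }
      out$beta[j] <- ff$beta[ncol(xj)]
      out$se[j] <- ff$se[ncol(xj)]
      out$flag[j] <- "firth"
    }
    out$p[j] <- 2 * stats::pnorm(-abs(out$beta[j] / out$se[j]))
  }
  attr(out, "method") <- "logistic_firth_standin"
  out
}

#' Genomic-control inflation factor
#' @param p association p-values
#' @return lambda_GC: median Wald chi-square over its null median
#' @export
lambda_gc <- function(p) {
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chisq, na.rm = TRUE) / stats::qchisq(0.5, df = 1)
}

#' Fixed-effect meta-analysis across region strata
#'
#' Inverse-variance pooling of per-stratum estimates with Cochran's Q and
#' I-squared heterogeneity statistics.
#'
#' @param beta,se per-stratum effect estimates and standard errors
#' @param het_p_threshold flag threshold on the Q-test p-value
#' @return list with `beta`, `se`, `p`, `q`, `q_p`, `i2`, `n_strata`,
#'   `heterogeneous`, `note`
#' @export
region_stratified_meta <- function(beta, se, het_p_threshold = 0.05) {
  ok <- !is.na(beta) & !is.na(se) & se > 0
  beta <- beta[ok]; se <- se[ok]
  k <- length(beta)
  if (k == 0) stop("no strata with estimates")
  if (k == 1)
    return(list(beta = beta, se = se,
                p = 2 * stats::pnorm(-abs(beta / se)), q = NA, q_p = NA,
                i2 = NA, n_strata = 1, heterogeneous = FALSE,
                note = "single stratum: pass-through"))
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- sqrt(1 / sum(w))
  q <- sum(w * (beta - b)^2)
  q_p <- stats::pchisq(q, df = k - 1, lower.tail = FALSE)
  i2 <- max(0, (q - (k - 1)) / q) * (q > 0)
  list(beta = b, se = s, p = 2 * stats::pnorm(-abs(b / s)), q = q, q_p = q_p,
       i2 = i2, n_strata = k, heterogeneous = q_p < het_p_threshold,
       note = NA_character_)
}

#' Greedy LD clumping of association results
#'
#' Repeatedly takes the most significant unassigned variant with p at or
#' below `p1` as a locus index and assigns to it every unassigned variant
#' within `kb` kilobases with r-squared at least `r2` and p at or below
#' `p2`. Index variants absent from the LD source are clumped by distance
#' only and flagged.
#'
#' @param results data.frame with `id`, `chrom`, `pos`, `p`
#' @param ld_calls genotype matrix for r-squared (columns named by variant
#'   id), or `NULL` for distance-only clumping
#' @param p1,kb,r2,p2 clumping parameters (defaults 5e-8 / 5000 / 0.05 /
#'   0.05)
#' @return `results` with added `locus` (index variant id or `NA`) and
#'   `is_index`; distance-only indices listed in attribute `no_ld_source`
#' @export
ld_clump <- function(results, ld_calls = NULL, p1 = 5e-8, kb = 5000,
                     r2 = 0.05, p2 = 0.05) {
  res <- results
  res$locus <- NA_character_
  res$is_index <- FALSE
  unassigned <- rep(TRUE, nrow(res))
  no_ld <- character(0)
  repeat {
    cand <- which(unassigned & res$p <= p1)
    if (!length(cand)) break
    idx <- cand[which.min(res$p[cand])]
    res$locus[idx] <- res$id[idx]
    res$is_index[idx] <- TRUE
    unassigned[idx] <- FALSE
    near <- which(unassigned & res$chrom == res$chrom[idx] &
                    abs(res$pos - res$pos[idx]) <= kb * 1000 &
                    res$p <= p2)
    if (length(near)) {
      have_ld <- !is.null(ld_calls) && res$id[idx] %in% colnames(ld_calls)
      if (!have_ld) {
        if (!is.null(ld_calls)) no_ld <- c(no_ld, res$id[idx])
        take <- near
      } else {
        gi <- ld_calls[, res$id[idx]]
        rr <- vapply(near, function(k) {
          if (!res$id[k] %in% colnames(ld_calls)) return(NA_real_)
          suppressWarnings(stats::cor(gi, ld_calls[, res$id[k]],
                                      use = "pairwise.complete.obs"))^2
        }, 0)
        take <- near[!is.na(rr) & rr >= r2]
      }
      res$locus[take] <- res$id[idx]
      unassigned[take] <- FALSE
    }
  }
  attr(res, "no_ld_source") <- no_ld
  res
}
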