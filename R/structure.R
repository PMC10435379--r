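# Population structure: LD pruning, PCA with projection, BIC-based
# informative-PC selection, the iterative HMM detector of long-range-LD
# regions in PC loadings, robust regional Mahalanobis outliers, local PCA,
# and pairwise Weir-Cockerham Fst.

#' Sliding-window LD pruning
#'
#' Windows of `window_snps` SNPs advanced by `step_snps`; within each window
#' one member of any pair with r-squared above the threshold is removed
#' (the lower-MAF variant; ties remove the later position) until no such
#' pair remains. Defaults correspond to the 50/5/0.2 recipe; the relatedness
#' pruning set uses 0.1.
#'
#' @param calls genotype matrix (samples x variants) or `genotype_dataset`
#' @param window_snps,step_snps,r2_threshold pruning parameters
#' @return indices of kept variants (into the columns of `calls`)
#' @export
ld_prune <- function(calls, window_snps = 50, step_snps = 5,
                     r2_threshold = 0.2) {
  if (inherits(calls, "genotype_dataset")) calls <- calls$calls
  m <- ncol(calls)
  keep <- rep(TRUE, m)
  mafs <- maf(calls)
  start <- 1
  repeat {
    end <- min(start + window_snps - 1, m)
    w <- which(keep[start:end]) + start - 1
    if (length(w) > 1) {
      r2 <- suppressWarnings(stats::cor(calls[, w, drop = FALSE],
                                        use = "pairwise.complete.obs"))^2
      repeat {
        r2na <- r2; r2na[!upper.tri(r2na)] <- NA
        bad <- which(r2na > r2_threshold, arr.ind = TRUE)
        if (!nrow(bad)) break
        pr <- bad[1, ]
        a <- w[pr[1]]; b <- w[pr[2]]
        drop_local <- if (mafs[a] < mafs[b]) pr[1]
          else if (mafs[b] < mafs[a]) pr[2]
          else pr[2]                        # tie: later position
        keep[w[drop_local]] <- FALSE
        r2[drop_local, ] <- NA; r2[, drop_local] <- NA
      }
    }
    if (end >= m) break
    start <- start + step_snps
  }
  which(keep)
}

#' Principal component analysis of a genotype matrix
#'
#' Genotypes are standardised per variant to mean `2p` and scale
#' `sqrt(2p(1-p))` with missing values set to zero after centring, then
#' decomposed by truncated SVD. Loadings and standardisation parameters are
#' retained so further samples can be projected.
#'
#' @param calls genotype matrix (samples x variants) or `genotype_dataset`
#' @param variant_idx optional column subset (e.g. an LD-pruned set)
#' @param n_pcs number of components
#' @return object of class `pca_result`: `scores` (n x k), `loadings`
#'   (m x k), `eigenvalues`, `variant_idx`, `center`, `scale`
#' @export
run_pca <- function(calls, variant_idx = NULL, n_pcs = 10) {
  if (inherits(calls, "genotype_dataset")) calls <- calls$calls
  if (is.null(variant_idx)) variant_idx <- seq_len(ncol(calls))
  g <- calls[, variant_idx, drop = FALSE]
  p <- colMeans(g, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1
  if (any(!poly)) {
    warning(sum(!poly), " monomorphic variant(s) dropped from PCA")
    g <- g[, poly, drop = FALSE]
    variant_idx <- variant_idx[poly]
    p <- p[poly]
  }
  ctr <- 2 * p
  scl <- sqrt(2 * p * (1 - p))
  x <- sweep(sweep(g, 2, ctr), 2, scl, `/`)
  x[is.na(x)] <- 0
  n_pcs <- min(n_pcs, nrow(x) - 1, ncol(x))
  sv <- svd(x, nu = 0, nv = n_pcs)
  loadings <- sv$v
  scores <- x %*% loadings
  rownames(scores) <- rownames(calls)
  structure(list(scores = scores, loadings = loadings,
                 eigenvalues = sv$d[seq_len(n_pcs)]^2 / (nrow(x) - 1),
                 variant_idx = variant_idx, center = ctr, scale = scl),
            class = "pca_result")
}

#' Project samples onto existing principal components
#'
#' New scores are the standardised genotypes (same per-variant centre and
#' scale as the training PCA) multiplied by the variant loadings; projecting
#' a training sample reproduces its PCA score.
#'
#' @param pca a [run_pca()] result
#' @param calls_new genotype matrix over the full original variant set, or
#'   already restricted to `pca$variant_idx` (matched by column count)
#' @param max_missing flag samples with more than this fraction missing on
#'   the PCA variant set (default 0.2)
#' @return score matrix with attribute `flagged` (high-missingness samples)
#' @export
project_samples <- function(pca, calls_new, max_missing = 0.2) {
  if (inherits(calls_new, "genotype_dataset")) calls_new <- calls_new$calls
  if (is.vector(calls_new)) calls_new <- matrix(calls_new, nrow = 1)
  g <- if (ncol(calls_new) == length(pca$variant_idx)) calls_new
    else calls_new[, pca$variant_idx, drop = FALSE]
  fmiss <- rowMeans(is.na(g))
  if (all(fmiss == 1)) stop("all genotypes missing on the projection set")
  x <- sweep(sweep(g, 2, pca$center), 2, pca$scale, `/`)
  x[is.na(x)] <- 0
  sc <- x %*% pca$loadings
  rownames(sc) <- rownames(calls_new)
  attr(sc, "flagged") <- which(fmiss > max_missing)
  sc
}

# BIC of a label model on a score matrix (columns = PCs used)
label_model_bic <- function(scores, labels, model) {
  n <- nrow(scores)
  df <- as.data.frame(scores)
  if (ncol(df)) names(df) <- paste0("PC", seq_len(ncol(df)))
  rhs <- if (ncol(df)) paste(names(df), collapse = " + ") else "1"
  if (model == "multinomial") {
    df$.y <- factor(labels)
    fit <- nnet::multinom(stats::as.formula(paste(".y ~", rhs)), data = df,
                          trace = FALSE, maxit = 200)
    return(fit$deviance + length(stats::coef(fit)) * log(n))
  }
  if (model == "binary") {
    df$.y <- labels
    fit <- stats::glm(stats::as.formula(paste(".y ~", rhs)), data = df,
                      family = stats::binomial())
    return(stats::BIC(fit))
  }
  if (model == "linear_2d") {
    # labels: 2-column matrix/data.frame (latitude, longitude)
    y <- as.matrix(labels)
    df$.y1 <- y[, 1]; df$.y2 <- y[, 2]
    b1 <- stats::BIC(stats::lm(stats::as.formula(paste(".y1 ~", rhs)), data = df))
    b2 <- stats::BIC(stats::lm(stats::as.formula(paste(".y2 ~", rhs)), data = df))
    return(b1 + b2)
  }
  stop("unknown model: ", model)
}

#' Select the informative leading principal components by BIC
#'
#' PCs are added in order to a model predicting the labels (multinomial for
#' region, paired linear models for latitude/longitude, binomial for a
#' binary label); k is the largest prefix in which every added PC reduced
#' the BIC.
#'
#' @param scores sample x PC score matrix
#' @param labels factor (multinomial/binary) or 2-column coordinates
#'   (linear_2d)
#' @param model `"multinomial"`, `"linear_2d"` or `"binary"`
#' @param max_pcs cap on the PCs considered
#' @return list with `k` and the `bic` trajectory (index 1 = no PCs)
#' @export
select_informative_pcs <- function(scores, labels,
                                   model = c("multinomial", "linear_2d",
                                             "binary"),
                                   max_pcs = ncol(scores)) {
  model <- match.arg(model)
  if (model != "linear_2d" && length(unique(stats::na.omit(labels))) < 2)
    return(list(k = 0, bic = numeric(0)))
  if (model == "linear_2d" && nrow(unique(as.data.frame(labels))) < 2)
    return(list(k = 0, bic = numeric(0)))
  max_pcs <- min(max_pcs, ncol(scores))
  bic <- numeric(max_pcs + 1)
  bic[1] <- label_model_bic(scores[, 0, drop = FALSE], labels, model)
  k <- 0
  for (j in seq_len(max_pcs)) {
    bic[j + 1] <- label_model_bic(scores[, seq_len(j), drop = FALSE], labels,
                                  model)
    if (bic[j + 1] < bic[j]) k <- j else break
  }
  list(k = k, bic = bic[seq_len(k + 1 + (k < max_pcs))])
}

# EM fit of a two-component scaled-chi-square(1) mixture to squared loading
# Z-scores: null component scale fixed at 1, inflated scale and weight free.
# Returns per-variant posterior of the inflated component, or NULL when the
# fit degenerates to a single component.
fit_z2_mixture <- function(z2, scale_floor = 3, max_iter = 200, tol = 1e-8) {
  z2 <- pmax(z2, 1e-12)
  w <- 0.05
  s <- max(stats::quantile(z2, 0.98) / stats::qchisq(0.98, 1), scale_floor)
  dscaled <- function(x, sc) stats::dchisq(x / sc, df = 1) / sc
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    f0 <- dscaled(z2, 1); f1 <- dscaled(z2, s)
    num <- w * f1
    den <- num + (1 - w) * f0
    r <- num / den
    w <- mean(r)
    s <- max(sum(r * z2) / max(sum(r), 1e-12), scale_floor)
    ll <- sum(log(den))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  if (w < 1e-6 || w > 0.999) return(NULL)
  f0 <- dscaled(z2, 1); f1 <- dscaled(z2, s)
  lrt <- 2 * (sum(log(w * f1 + (1 - w) * f0)) - sum(log(f0)))
  # per-variant evidence is the equal-weight component posterior
  # f1/(f0 + f1): the mixing weight must not enter the HMM emission, because
  # the chain's stationary prior already carries it -- multiplying a run of
  # L in-state variants by w^L would make long regions nearly unreachable
  list(evidence = f1 / (f1 + f0),
       posterior = w * f1 / (w * f1 + (1 - w) * f0), weight = w, scale = s,
       lrt = lrt)
}

# forward-backward posteriors for the two-state LRLD HMM.
# emis: n x 2 matrix of per-variant emission likelihoods (out, in);
# delta_cm: n-1 genetic distances between adjacent variants.
hmm_posterior <- function(emis, delta_cm, rho = 1, pi_in = 0.05) {
  n <- nrow(emis)
  init <- c(1 - pi_in, pi_in)
  sw <- 1 - exp(-rho * pmax(delta_cm, 1e-6))
  alpha <- matrix(0, n, 2); beta <- matrix(0, n, 2)
  cvec <- numeric(n)
  a <- init * emis[1, ]
  cvec[1] <- sum(a); alpha[1, ] <- a / cvec[1]
  trans <- function(k) {
    # switch probabilities balanced to the stationary prior
    a01 <- pi_in * sw[k]; a10 <- (1 - pi_in) * sw[k]
    matrix(c(1 - a01, a01, a10, 1 - a10), 2, 2, byrow = TRUE)
  }
  for (t in 2:n) {
    Tm <- trans(t - 1)
    a <- (alpha[t - 1, ] %*% Tm) * emis[t, ]
    cvec[t] <- sum(a)
    alpha[t, ] <- a / cvec[t]
  }
  beta[n, ] <- 1
  for (t in (n - 1):1) {
    Tm <- trans(t)
    b <- Tm %*% (emis[t + 1, ] * beta[t + 1, ])
    beta[t, ] <- b / cvec[t + 1]
  }
  post <- alpha * beta
  post / rowSums(post)
}

#' Default HMM parameters for long-range-LD detection
#' @param rho switch rate per cM
#' @param pi_in stationary prior probability of the in-region state
#' @param posterior_threshold region membership threshold
#' @param merge_bp regions closer than this are merged (default 1 Mbp)
#' @param scale_floor lower bound on the inflated emission-mixture scale
#' @param min_mixture_lrt minimum likelihood-ratio statistic of the
#'   two-component loading mixture against the pure null before a PC is
#'   scanned; guards against spurious regions when the loadings show no
#'   inflation at all (default 6)
#' @return list of class `hmm_params`
#' @export
hmm_params <- function(rho = 1, pi_in = 0.05, posterior_threshold = 0.5,
                       merge_bp = 1e6, scale_floor = 3, min_mixture_lrt = 6) {
  stopifnot(rho > 0, pi_in > 0, pi_in < 1, posterior_threshold > 0,
            posterior_threshold < 1)
  structure(list(rho = rho, pi_in = pi_in,
                 posterior_threshold = posterior_threshold,
                 merge_bp = merge_bp, scale_floor = scale_floor,
                 min_mixture_lrt = min_mixture_lrt),
            class = "hmm_params")
}

#' Detect long-range-LD regions on one PC by a two-state HMM
#'
#' The hidden state is presence within/outside a long-range-LD region;
#' transitions between adjacent variants follow the recombination map
#' (switch probability `1 - exp(-rho * d_cM)`, balanced to the stationary
#' prior); the emission is the posterior probability of the inflated
#' component of a two-component scaled-chi-square mixture fitted to the
#' squared loading Z-scores. Variants with marginal posterior above the
#' threshold form runs; runs on one chromosome closer than the merge
#' distance are merged.
#'
#' @param loadings per-variant loadings on one PC
#' @param variants variant map (`chrom`, `pos`) aligned with `loadings`
#' @param map genetic map (see [uniform_genetic_map()])
#' @param params an [hmm_params()]
#' @return data.frame of regions (`chrom`, `start`, `end`, `peak_posterior`,
#'   `n_variants`), plus per-variant posteriors as attribute `posterior`
#' @export
detect_lrld_hmm <- function(loadings, variants, map, params = hmm_params()) {
  z <- (loadings - mean(loadings)) / stats::sd(loadings)
  mix <- fit_z2_mixture(z^2, scale_floor = params$scale_floor)
  post_all <- rep(0, length(z))
  regions <- list()
  if (!is.null(mix) && mix$lrt < params$min_mixture_lrt) mix <- NULL
  if (is.null(mix)) {
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), peak_posterior = numeric(0),
                      n_variants = integer(0))
    attr(out, "posterior") <- post_all
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  e_in <- mix$evidence
  for (ch in unique(variants$chrom)) {
    i <- which(variants$chrom == ch)
    if (length(i) < 100) next
    cm <- interp_cm(map, variants$chrom[i], variants$pos[i])
    emis <- cbind(1 - e_in[i], e_in[i])
    post <- hmm_posterior(emis, diff(cm), rho = params$rho,
                          pi_in = params$pi_in)[, 2]
    post_all[i] <- post
    hot <- post > params$posterior_threshold
    if (!any(hot)) next
    run_id <- cumsum(c(TRUE, diff(hot) != 0))
    pos <- variants$pos[i]
    runs <- lapply(unique(run_id[hot]), function(rid) {
      j <- which(hot & run_id == rid)
      # boundaries: outermost hot variants extended halfway to neighbours
      lo <- if (min(j) > 1) (pos[min(j)] + pos[min(j) - 1]) / 2 else pos[min(j)]
      hi <- if (max(j) < length(pos)) (pos[max(j)] + pos[max(j) + 1]) / 2
        else pos[max(j)]
      data.frame(chrom = ch, start = lo, end = hi,
                 peak_posterior = max(post[j]), n_variants = length(j))
    })
    runs <- do.call(rbind, runs)
    # merge runs closer than merge_bp
    if (nrow(runs) > 1) {
      runs <- runs[order(runs$start), ]
      merged <- runs[1, ]
      for (k in 2:nrow(runs)) {
        last <- nrow(merged)
        if (runs$start[k] - merged$end[last] < params$merge_bp) {
          merged$end[last] <- runs$end[k]
          merged$peak_posterior[last] <- max(merged$peak_posterior[last],
                                             runs$peak_posterior[k])
          merged$n_variants[last] <- merged$n_variants[last] + runs$n_variants[k]
        } else merged <- rbind(merged, runs[k, ])
      }
      runs <- merged
    }
    regions[[length(regions) + 1]] <- runs
  }
  out <- if (length(regions)) do.call(rbind, regions) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               peak_posterior = numeric(0), n_variants = integer(0))
  rownames(out) <- NULL
  attr(out, "posterior") <- post_all
  out
}

#' Iterative PCA with HMM-based long-range-LD removal
#'
#' Alternates PCA on the current variant set with HMM scans of the leading
#' informative PCs (plus one non-informative control PC); variants inside
#' newly detected regions are excluded and the PCA repeated until no new
#' region is found in any scanned PC or the iteration cap is reached.
#'
#' @param calls genotype matrix
#' @param variants variant map aligned with the columns of `calls`
#' @param pruned_idx starting LD-pruned variant indices
#' @param map genetic map
#' @param labels region labels for informative-PC selection (`NULL` scans a
#'   fixed `n_scan_pcs`)
#' @param params an [hmm_params()]
#' @param n_pcs PCs computed per iteration
#' @param n_scan_pcs PCs scanned when `labels` is `NULL`
#' @param seed_exclusions optional data.frame of previously known regions
#'   (`chrom`, `start`, `end`) excluded before the first iteration
#' @param max_iter iteration cap
#' @return list with `pca` (final), `regions` (cumulative, per-chromosome
#'   disjoint), `kept_idx`, `n_iter`, `k_informative`
#' @export
iterate_lrld_pca <- function(calls, variants, pruned_idx, map, labels = NULL,
                             params = hmm_params(), n_pcs = 10,
                             n_scan_pcs = 3, seed_exclusions = NULL,
                             max_iter = 10) {
  in_region <- function(v, reg) {
    hit <- rep(FALSE, nrow(v))
    for (k in seq_len(nrow(reg)))
      hit <- hit | (v$chrom == reg$chrom[k] & v$pos >= reg$start[k] &
                      v$pos <= reg$end[k])
    hit
  }
  idx <- pruned_idx
  if (!is.null(seed_exclusions) && nrow(seed_exclusions))
    idx <- idx[!in_region(variants[idx, ], seed_exclusions)]
  all_regions <- list()
  pca <- NULL; k_inf <- NA
  for (it in seq_len(max_iter)) {
    pca <- run_pca(calls, idx, n_pcs = n_pcs)
    if (!is.null(labels)) {
      k_inf <- select_informative_pcs(pca$scores, labels, "multinomial")$k
      scan <- seq_len(min(k_inf + 1, ncol(pca$scores)))
    } else scan <- seq_len(min(n_scan_pcs, ncol(pca$scores)))
    new_regions <- list()
    for (pc in scan) {
      reg <- detect_lrld_hmm(pca$loadings[, pc], variants[pca$variant_idx, ],
                             map, params)
      if (nrow(reg)) {
        reg$pc <- pc; reg$iteration <- it
        new_regions[[length(new_regions) + 1]] <- reg
      }
    }
    if (!length(new_regions)) break
    newr <- do.call(rbind, new_regions)
    all_regions[[length(all_regions) + 1]] <- newr
    idx <- idx[!in_region(variants[idx, ], newr)]
    if (it == max_iter)
      warning("iteration cap reached with regions still being found")
  }
  regions <- if (length(all_regions)) do.call(rbind, all_regions) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               peak_posterior = numeric(0), n_variants = integer(0),
               pc = integer(0), iteration = integer(0))
  # merge cumulative regions into disjoint intervals per chromosome
  if (nrow(regions) > 1) {
    merged <- list()
    for (ch in unique(regions$chrom)) {
      r <- regions[regions$chrom == ch, ]
      r <- r[order(r$start), ]
      cur <- r[1, ]
      for (k in seq_len(nrow(r))[-1]) {
        if (r$start[k] <= cur$end + params$merge_bp) {
          cur$end <- max(cur$end, r$end[k])
          cur$peak_posterior <- max(cur$peak_posterior, r$peak_posterior[k])
          cur$n_variants <- cur$n_variants + r$n_variants[k]
        } else { merged[[length(merged) + 1]] <- cur; cur <- r[k, ] }
      }
      merged[[length(merged) + 1]] <- cur
    }
    regions <- do.call(rbind, merged)
    rownames(regions) <- NULL
  }
  list(pca = pca, regions = regions, kept_idx = idx, n_iter = it,
       k_informative = k_inf)
}

#' Robust regional ancestry outliers (non-local ancestry)
#'
#' Per recruitment region, a robust location/scatter (minimum covariance
#' determinant with 75% support) is fitted on the informative PCs and
#' samples with a Mahalanobis distance beyond the 3-SD-equivalent
#' chi-square quantile are flagged. Singular scatter falls back to a
#' per-PC |Z| > 3 rule.
#'
#' @param scores sample x PC score matrix
#' @param region_ids per-sample region labels
#' @param k number of informative PCs used
#' @param sd_threshold threshold in SD-equivalents (default 3)
#' @param min_region_n minimum region size (default 50)
#' @return data.frame with `distance` (SD-equivalent) and `flag`
#' @export
regional_outliers <- function(scores, region_ids, k = ncol(scores),
                              sd_threshold = 3, min_region_n = 50) {
  k <- min(k, ncol(scores))
  x <- scores[, seq_len(k), drop = FALSE]
  n <- nrow(x)
  dist <- rep(NA_real_, n); flag <- rep(FALSE, n)
  # SD-equivalent: the chi-square quantile matching the two-sided normal
  # tail mass of +/- sd_threshold
  pmass <- 1 - 2 * stats::pnorm(-sd_threshold)
  cut2 <- stats::qchisq(pmass, df = k)
  for (r in unique(region_ids)) {
    i <- which(region_ids == r)
    if (length(i) < min_region_n) {
      warning("region ", r, " below ", min_region_n, " samples; skipped")
      next
    }
    xi <- x[i, , drop = FALSE]
    d2 <- tryCatch({
      mcd <- MASS::cov.mcd(xi, quantile.used = floor(0.75 * length(i)))
      stats::mahalanobis(xi, mcd$center, mcd$cov)
    }, error = function(e) NULL)
    if (is.null(d2)) {      # singular scatter: per-PC robust Z rule
      zz <- abs(scale(xi, center = apply(xi, 2, stats::median),
                      scale = apply(xi, 2, stats::mad)))
      d2 <- apply(zz, 1, max)^2
      dist[i] <- sqrt(d2)
      flag[i] <- dist[i] > sd_threshold
      next
    }
    dist[i] <- sqrt(d2)
    flag[i] <- d2 > cut2
  }
  data.frame(distance = dist, flag = flag)
}

#' Within-region PCA with geographic informativeness
#'
#' PCA restricted to one region's samples (ancestry outliers removed by the
#' caller), with the number of informative PCs chosen by BIC against the
#' latitude/longitude of the assessment centres.
#'
#' @param calls genotype matrix of the region's samples
#' @param coords 2-column latitude/longitude per sample
#' @param variant_idx optional variant subset
#' @param n_pcs components to compute
#' @return list with `pca` and `k`
#' @export
local_pca <- function(calls, coords, variant_idx = NULL, n_pcs = 10) {
  pca <- run_pca(calls, variant_idx, n_pcs = n_pcs)
  if (nrow(unique(as.data.frame(coords))) < 2)
    return(list(pca = pca, k = 0))
  sel <- select_informative_pcs(pca$scores, coords, model = "linear_2d")
  list(pca = pca, k = sel$k)
}

# Weir-Cockerham variance components for one variant across r populations
wc_components <- function(nn, pp, hh) {
  r <- length(nn)
  nbar <- mean(nn)
  nc <- (r * nbar - sum(nn^2) / (r * nbar)) / (r - 1)
  pbar <- sum(nn * pp) / (r * nbar)
  s2 <- sum(nn * (pp - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(nn * hh) / (r * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                      (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

#' Pairwise Weir-Cockerham Fst between regions
#'
#' Ratio-of-sums estimator across variants for each pair of regions;
#' negative estimates are reported as computed. Variants are pre-filtered
#' to MAF above `maf_min` across the two regions of each pair.
#'
#' @param calls genotype matrix (samples x variants)
#' @param region_ids per-sample region labels
#' @param maf_min minor-allele-frequency filter (default 0.01)
#' @return symmetric Fst matrix with zero diagonal
#' @export
fst_matrix <- function(calls, region_ids, maf_min = 0.01) {
  if (inherits(calls, "genotype_dataset")) calls <- calls$calls
  regions <- sort(unique(region_ids))
  if (length(regions) < 2) stop("need at least 2 regions")
  small <- regions[table(factor(region_ids, levels = regions)) < 20]
  if (length(small))
    warning("region(s) with fewer than 20 samples: ",
            paste(small, collapse = ", "))
  nr <- length(regions)
  out <- matrix(0, nr, nr, dimnames = list(regions, regions))
  stats_by_region <- lapply(regions, function(r) {
    g <- calls[region_ids == r, , drop = FALSE]
    nn <- colSums(!is.na(g))
    list(n = nn, p = colMeans(g, na.rm = TRUE) / 2,
         h = colMeans(g == 1L, na.rm = TRUE))
  })
  names(stats_by_region) <- regions
  for (i in seq_len(nr - 1)) for (j in (i + 1):nr) {
    si <- stats_by_region[[i]]; sj <- stats_by_region[[j]]
    ptot <- (si$n * si$p + sj$n * sj$p) / (si$n + sj$n)
    ok <- si$n > 1 & sj$n > 1 & pmin(ptot, 1 - ptot) > maf_min
    comp <- vapply(which(ok), function(v)
      wc_components(c(si$n[v], sj$n[v]), c(si$p[v], sj$p[v]),
                    c(si$h[v], sj$h[v])), c(a = 0, b = 0, c = 0))
    fst <- sum(comp["a", ]) / sum(comp["a", ] + comp["b", ] + comp["c", ])
    out[i, j] <- out[j, i] <- fst
  }
  out
}
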