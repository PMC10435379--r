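# Variant-level QC: initial plate QC, plate/batch genotype-calling effect
# tests with the empirically derived fail rules, region-stratified HWE,
# reference-frequency concordance, duplicate-probeset resolution.

#' Initial plate-level quality control
#'
#' Excludes samples with DQC < 0.82 or QC call rate < 97%, then plates whose
#' remaining samples have a mean call rate < 98.5%; plates with a sample
#' pass rate < 95% are flagged for manual inspection.
#'
#' @param sample_metrics data.frame with `sample_id`, `plate`, `dqc`,
#'   `qc_callrate`
#' @param dqc_min,callrate_min,plate_callrate_min,plate_passrate_min rule
#'   thresholds
#' @return list with `excluded_samples` (id + reason), `excluded_plates`,
#'   `flagged_plates`
#' @export
initial_plate_qc <- function(sample_metrics, dqc_min = 0.82,
                             callrate_min = 0.97, plate_callrate_min = 0.985,
                             plate_passrate_min = 0.95) {
  sm <- sample_metrics
  fail_dqc <- sm$dqc < dqc_min
  fail_cr <- sm$qc_callrate < callrate_min
  fail <- fail_dqc | fail_cr
  excluded_samples <- data.frame(
    sample_id = sm$sample_id[fail],
    reason = ifelse(fail_dqc[fail], "low_dqc", "low_callrate"),
    stringsAsFactors = FALSE)
  plates <- sort(unique(sm$plate))
  excluded_plates <- integer(0); flagged_plates <- integer(0)
  for (p in plates) {
    on <- sm$plate == p
    rem <- on & !fail
    if (!any(on)) next
    if (!any(rem)) { flagged_plates <- c(flagged_plates, p); next }  # empty plate
    if (mean(sm$qc_callrate[rem]) < plate_callrate_min)
      excluded_plates <- c(excluded_plates, p)
    if (mean(!fail[on]) < plate_passrate_min)
      flagged_plates <- c(flagged_plates, p)
  }
  list(excluded_samples = excluded_samples,
       excluded_plates = excluded_plates,
       flagged_plates = flagged_plates)
}

# likelihood-ratio test of genotype in a logistic model of group membership
# with a region covariate. The default genotype-class encoding (one indicator
# per genotype class, 1-2 df) is sensitive to heterozygote-cluster collapse,
# which barely moves the dosage mean; encoding = "dosage" gives the 1-df
# additive test. Returns p or NA with a flag.
genotype_lrt <- function(y, g, region, encoding = "genotype_class") {
  ok <- !is.na(g)
  y <- y[ok]; g <- g[ok]
  region <- droplevels(factor(region[ok]))
  if (length(unique(g)) < 2) return(list(p = NA_real_, flag = "monomorphic"))
  if (length(unique(y)) < 2) return(list(p = NA_real_, flag = "degenerate_groups"))
  x0 <- if (nlevels(region) > 1) stats::model.matrix(~region) else
    matrix(1, length(y), 1)
  xg <- if (encoding == "dosage") cbind(g) else
    stats::model.matrix(~factor(g))[, -1, drop = FALSE]
  fit1 <- tryCatch(
    suppressWarnings(stats::glm.fit(cbind(x0, xg), y,
                                    family = stats::binomial())),
    error = function(e) NULL)
  fit0 <- tryCatch(
    suppressWarnings(stats::glm.fit(x0, y, family = stats::binomial())),
    error = function(e) NULL)
  if (is.null(fit1) || is.null(fit0) || !fit1$converged || !fit0$converged)
    return(list(p = NA_real_, flag = "nonconverged"))
  lr <- fit0$deviance - fit1$deviance
  df <- ncol(xg)
  list(p = stats::pchisq(max(lr, 0), df = df, lower.tail = FALSE),
       flag = NA_character_)
}

#' Per-plate genotype-calling effect test
#'
#' Each plate in turn is treated as "case" status against all other plates
#' in the batch, in a logistic regression of plate membership on genotype
#' dosage with recruitment region as covariate (1-df likelihood-ratio test).
#'
#' @param calls genotype matrix restricted to one batch (samples x variants)
#' @param plate_ids,region_ids per-sample plate and region labels
#' @param encoding `"genotype_class"` (default; indicators per genotype
#'   class, sensitive to heterozygote-cluster collapse) or `"dosage"`
#'   (1-df additive)
#' @return list with `p` (plates x variants matrix) and `flags` (same shape,
#'   `NA`, `"monomorphic"` or `"nonconverged"`)
#' @export
plate_effect_test <- function(calls, plate_ids, region_ids,
                              encoding = c("genotype_class", "dosage")) {
  encoding <- match.arg(encoding)
  plates <- sort(unique(plate_ids))
  if (length(plates) < 2) stop("need at least 2 plates")
  m <- ncol(calls)
  p <- matrix(NA_real_, length(plates), m,
              dimnames = list(as.character(plates), colnames(calls)))
  flags <- matrix(NA_character_, length(plates), m,
                  dimnames = dimnames(p))
  for (j in seq_len(m)) {
    g <- calls[, j]
    if (length(unique(g[!is.na(g)])) < 2) {
      flags[, j] <- "monomorphic"
      next
    }
    for (k in seq_along(plates)) {
      y <- as.integer(plate_ids == plates[k])
      r <- genotype_lrt(y, g, region_ids, encoding)
      p[k, j] <- r$p
      flags[k, j] <- r$flag
    }
  }
  list(p = p, flags = flags)
}

#' Apply the plate-effect fail rules to one probeset
#'
#' Fail iff any plate effect p < 1e-10, or more than 3 plates with
#' p < 1e-4, or any plate effect p < 1e-8 together with clustering metrics
#' FLD < 8, HetSO < 0.68 and HomRO < 3.7. Probesets with any plate effect
#' p < 2e-5 that do not fail are flagged for cluster-plot review, as are
#' probesets in the metric-dependent band whose metrics are missing.
#'
#' @param plate_pvalues numeric vector of per-plate p-values for the probeset
#' @param fld,hetso,homro clustering metrics for the probeset in this batch
#'   (may be `NA`)
#' @return list with `fail` (logical), `reason`, `review` (logical)
#' @export
apply_plate_fail_rules <- function(plate_pvalues, fld = NA, hetso = NA,
                                   homro = NA) {
  pv <- plate_pvalues[!is.na(plate_pvalues)]
  if (!length(pv)) return(list(fail = FALSE, reason = NA_character_,
                               review = FALSE))
  minp <- min(pv)
  if (minp < 1e-10)
    return(list(fail = TRUE, reason = "plate_p_lt_1e-10", review = FALSE))
  if (sum(pv < 1e-4) > 3)
    return(list(fail = TRUE, reason = "gt3_plates_p_lt_1e-4", review = FALSE))
  if (minp < 1e-8) {
    if (any(is.na(c(fld, hetso, homro))))
      return(list(fail = FALSE, reason = "metrics_missing", review = TRUE))
    if (fld < 8 && hetso < 0.68 && homro < 3.7)
      return(list(fail = TRUE, reason = "plate_p_lt_1e-8_poor_clustering",
                  review = FALSE))
  }
  if (minp < 2e-5)
    return(list(fail = FALSE, reason = "manual_review_band", review = TRUE))
  list(fail = FALSE, reason = NA_character_, review = FALSE)
}

#' Batch-level genotype-calling effect test
#'
#' Each batch in turn is treated as "case" against all other batches, using
#' unrelated samples only, with region as covariate. A probeset fails if any
#' batch effect has p < 1e-10, or if the count of batches with p < 1e-4
#' exceeds the array-version-specific limit (2 for version 1, 7 for
#' version 2).
#'
#' @param calls genotype matrix (samples x variants)
#' @param batch_ids,region_ids per-sample labels
#' @param unrelated_mask logical: samples in the unrelated set
#' @param array_version 1 or 2 (sets the multi-batch limit)
#' @param encoding genotype encoding, as in [plate_effect_test()]
#' @return list with `p` (batches x variants), `fail`, `reason`, `review`
#'   (batch-effect p < 1e-3 band for manual scoring)
#' @export
batch_effect_test <- function(calls, batch_ids, region_ids, unrelated_mask,
                              array_version = 1,
                              encoding = c("genotype_class", "dosage")) {
  encoding <- match.arg(encoding)
  keep <- unrelated_mask
  res <- plate_effect_test(calls[keep, , drop = FALSE], batch_ids[keep],
                           region_ids[keep], encoding)
  m <- ncol(res$p)
  fail <- logical(m); reason <- rep(NA_character_, m); review <- logical(m)
  for (j in seq_len(m)) {
    r <- apply_batch_fail_rules(res$p[, j], array_version)
    fail[j] <- r$fail; reason[j] <- r$reason; review[j] <- r$review
  }
  names(fail) <- names(reason) <- names(review) <- colnames(res$p)
  list(p = res$p, fail = fail, reason = reason, review = review)
}

#' Apply the batch-effect fail rules to one probeset
#'
#' Fail iff any batch effect p < 1e-10, or the count of batches with
#' p < 1e-4 exceeds the array-version limit (more than 2 for version 1,
#' more than 7 for version 2). Remaining probesets with any batch p < 1e-3
#' are flagged for manual cluster scoring.
#'
#' @param batch_pvalues per-batch p-values for the probeset
#' @param array_version 1 or 2
#' @return list with `fail`, `reason`, `review`
#' @export
apply_batch_fail_rules <- function(batch_pvalues, array_version = 1) {
  limit <- if (array_version == 1) 2 else 7
  pv <- batch_pvalues[!is.na(batch_pvalues)]
  if (!length(pv)) return(list(fail = FALSE, reason = NA_character_,
                               review = FALSE))
  if (min(pv) < 1e-10)
    return(list(fail = TRUE, reason = "batch_p_lt_1e-10", review = FALSE))
  if (sum(pv < 1e-4) > limit)
    return(list(fail = TRUE, reason = paste0("gt", limit, "_batches_p_lt_1e-4"),
                review = FALSE))
  list(fail = FALSE, reason = NA_character_, review = min(pv) < 1e-3)
}

# 1-df HWE chi-square from genotype counts (n0, n1, n2 = copies of counted
# allele); returns 0 with df contribution 0 for degenerate counts
hwe_chisq_counts <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (n < 2) return(c(stat = 0, df = 0))
  p <- (2 * n2 + n1) / (2 * n)
  if (p <= 0 || p >= 1) return(c(stat = 0, df = 0))
  q <- 1 - p
  e <- n * c(q^2, 2 * p * q, p^2)
  c(stat = sum((c(n0, n1, n2) - e)^2 / e), df = 1)
}

#' Region-stratified Hardy-Weinberg test
#'
#' Per-region 1-df chi-square statistics from genotype counts, summed over
#' regions; the p-value uses a chi-square with degrees of freedom equal to
#' the number of contributing regions (10 in the full study design; regions
#' with fewer than 2 genotyped samples or monomorphic counts contribute 0
#' with reduced df). For chrX variants only females are used.
#'
#' @param calls genotype vector or matrix (samples x variants)
#' @param region_ids per-sample region labels
#' @param sex per-sample sex (`"M"`/`"F"`), required for chrX
#' @param chromosome `"autosome"` or `"X"`
#' @param p_threshold exclusion threshold (default 1e-6)
#' @return data.frame with `stat`, `df`, `p`, `fail` per variant
#' @export
hwe_region_test <- function(calls, region_ids, sex = NULL,
                            chromosome = "autosome", p_threshold = 1e-6) {
  if (is.vector(calls)) calls <- matrix(calls, ncol = 1)
  if (identical(chromosome, "X")) {
    if (is.null(sex)) stop("sex required for chrX HWE testing")
    keep <- !is.na(sex) & sex == "F"
    calls <- calls[keep, , drop = FALSE]
    region_ids <- region_ids[keep]
  }
  regions <- sort(unique(region_ids))
  out <- data.frame(stat = numeric(ncol(calls)), df = integer(ncol(calls)),
                    p = numeric(ncol(calls)), fail = logical(ncol(calls)))
  for (j in seq_len(ncol(calls))) {
    stat <- 0; df <- 0
    for (r in regions) {
      g <- calls[region_ids == r, j]
      g <- g[!is.na(g)]
      res <- hwe_chisq_counts(sum(g == 0L), sum(g == 1L), sum(g == 2L))
      stat <- stat + res["stat"]; df <- df + res["df"]
    }
    p <- if (df > 0) stats::pchisq(stat, df, lower.tail = FALSE) else NA_real_
    out$stat[j] <- stat; out$df[j] <- df; out$p[j] <- p
    out$fail[j] <- !is.na(p) && p < p_threshold
  }
  rownames(out) <- colnames(calls)
  out
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Reference allele-frequency concordance filter
#'
#' Harmonises dataset alleles with a reference panel (direct match, allele
#' swap, strand flip, or both) and drops variants whose MAF differs from the
#' reference MAF by more than `max_diff`. Strand-ambiguous (A/T, C/G) pairs
#' are matched without flipping only when both MAFs are below 0.4, otherwise
#' flagged ambiguous and dropped from the comparison. Multiallelic reference
#' sites and unmatched alleles are dropped; variants absent from the
#' reference are flagged and retained.
#'
#' @param dataset_afs data.frame `chrom`, `pos`, `a1`, `a2`, `af`
#'   (counted-allele frequency of `a1`)
#' @param reference_afs data.frame `chrom`, `pos`, `a1`, `a2`, `af`
#' @param max_diff maximum tolerated |MAF - reference MAF| (default 0.2)
#' @return input data.frame with added `status` (`keep`, `drop_maf`,
#'   `drop_mismatch`, `drop_multiallelic`, `drop_ambiguous`, `no_reference`),
#'   `orientation` and `ref_maf`
#' @export
reference_maf_filter <- function(dataset_afs, reference_afs, max_diff = 0.2) {
  d <- dataset_afs
  key <- function(x) paste(x$chrom, x$pos, sep = ":")
  rkey <- key(reference_afs)
  multi <- rkey[duplicated(rkey)]
  d$status <- NA_character_; d$orientation <- NA_character_
  d$ref_maf <- NA_real_
  dk <- key(d)
  idx <- match(dk, rkey)
  for (i in seq_len(nrow(d))) {
    if (dk[i] %in% multi) { d$status[i] <- "drop_multiallelic"; next }
    if (is.na(idx[i])) { d$status[i] <- "no_reference"; next }
    r <- reference_afs[idx[i], ]
    a1 <- toupper(d$a1[i]); a2 <- toupper(d$a2[i])
    ambiguous <- a2 == COMPLEMENT[a1]
    f1 <- toupper(unname(COMPLEMENT[a1])); f2 <- toupper(unname(COMPLEMENT[a2]))
    ref_af_of_a1 <- NA_real_; orient <- NA_character_
    if (r$a1 == a1 && r$a2 == a2) { ref_af_of_a1 <- r$af; orient <- "direct" }
    else if (r$a1 == a2 && r$a2 == a1) { ref_af_of_a1 <- 1 - r$af; orient <- "swap" }
    else if (!ambiguous && r$a1 == f1 && r$a2 == f2) {
      ref_af_of_a1 <- r$af; orient <- "flip"
    } else if (!ambiguous && r$a1 == f2 && r$a2 == f1) {
      ref_af_of_a1 <- 1 - r$af; orient <- "flip_swap"
    }
    if (is.na(orient)) { d$status[i] <- "drop_mismatch"; next }
    maf_d <- min(d$af[i], 1 - d$af[i])
    maf_r <- min(ref_af_of_a1, 1 - ref_af_of_a1)
    if (ambiguous && !(maf_d < 0.4 && maf_r < 0.4)) {
      d$status[i] <- "drop_ambiguous"; next
    }
    d$orientation[i] <- orient
    d$ref_maf[i] <- maf_r
    d$status[i] <- if (abs(maf_d - maf_r) > max_diff) "drop_maf" else "keep"
  }
  d
}

#' Resolve duplicate probesets assaying the same variant
#'
#' Per variant, the probeset with the highest call rate is retained; exact
#' ties are broken by lexicographic probeset id and logged.
#'
#' @param probesets data.frame with `variant_id`, `probeset`, `call_rate`
#' @return input with logical `retained` column and a `ties` attribute
#'   listing tie-broken variant ids
#' @export
resolve_duplicate_probesets <- function(probesets) {
  ps <- probesets
  ps$retained <- FALSE
  ties <- character(0)
  for (v in unique(ps$variant_id)) {
    i <- which(ps$variant_id == v)
    best <- i[order(-ps$call_rate[i], ps$probeset[i])][1]
    if (sum(ps$call_rate[i] == ps$call_rate[best]) > 1) ties <- c(ties, v)
    ps$retained[best] <- TRUE
  }
  attr(ps, "ties") <- ties
  ps
}

#' Compile a per-variant QC report
#'
#' One primary status per variant in pipeline order (initial, plate, batch,
#' HWE, reference MAF, call rate, duplicate probeset); every failed variant
#' carries the statistic that triggered the decision. Applying the report to
#' its own pass set is idempotent.
#'
#' @param variants variant map data.frame (column `id`)
#' @param initial_fail,plate_fail,batch_fail,hwe_fail,refmaf_fail,
#'   callrate_fail,duplicate_fail logical vectors (default all `FALSE`)
#' @param stats optional data.frame of supporting statistics (min plate p,
#'   HWE stat, MAF difference, ...) cbound onto the report
#' @return data.frame with `id`, `status` and any supporting statistics
#' @export
compile_variant_report <- function(variants,
                                   initial_fail = FALSE, plate_fail = FALSE,
                                   batch_fail = FALSE, hwe_fail = FALSE,
                                   refmaf_fail = FALSE, callrate_fail = FALSE,
                                   duplicate_fail = FALSE, stats = NULL) {
  m <- nrow(variants)
  f <- function(x) rep_len(x, m)
  status <- rep("pass", m)
  rules <- list(fail_duplicate = f(duplicate_fail),
                fail_callrate = f(callrate_fail),
                fail_refmaf = f(refmaf_fail),
                fail_hwe = f(hwe_fail),
                fail_batch = f(batch_fail),
                fail_plate = f(plate_fail),
                fail_initial = f(initial_fail))
  for (nm in names(rules)) status[rules[[nm]]] <- nm  # later = higher priority
  out <- data.frame(id = variants$id, status = status, stringsAsFactors = FALSE)
  if (!is.null(stats)) out <- cbind(out, stats)
  out
}
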