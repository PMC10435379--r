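# Sample-level QC: region-standardised heterozygosity with the ROH rescue
# rule, ROH detection, sex inference and chrX aneuploidy karyotyping from
# intensity summaries, plate-orientation tracing, ancestry outliers,
# duplicate discovery, and the consolidated exclusion ledger.

#' Region-standardised heterozygosity outliers
#'
#' Heterozygosity shows a strong geographic gradient, so Z-scores are
#' computed within recruitment region; samples with Z > +3 are flagged for
#' exclusion (excess heterozygosity, e.g. sample contamination).
#'
#' @param het per-sample autosomal heterozygosity fractions
#' @param region_ids per-sample region labels
#' @param min_region_n regions below this size yield no Z (warning)
#' @param z_threshold exclusion threshold on the upper tail
#' @return data.frame with `z` and logical `fail_het_high`
#' @export
heterozygosity_outliers <- function(het, region_ids, min_region_n = 20,
                                    z_threshold = 3) {
  z <- rep(NA_real_, length(het))
  for (r in unique(region_ids)) {
    i <- which(region_ids == r)
    if (length(i) < min_region_n) {
      warning("region ", r, " has ", length(i),
              " samples (< ", min_region_n, "); no heterozygosity Z computed")
      next
    }
    s <- stats::sd(het[i])
    z[i] <- if (s > 0) (het[i] - mean(het[i])) / s else 0
  }
  data.frame(z = z, fail_het_high = !is.na(z) & z > z_threshold)
}

#' Low-heterozygosity exclusion with the ROH rescue rule
#'
#' Samples more than 3 SDs below their region's mean heterozygosity are
#' excluded only when the deficit is not explained by autozygosity: the rule
#' is het Z < -3 AND ROH Z < 2. Consanguineous samples (low het, extensive
#' runs of homozygosity) are retained.
#'
#' @param het_z region-standardised heterozygosity Z-scores
#' @param roh_z region-standardised Z-scores of total ROH length
#' @return data.frame with `fail_hom_low` and `review` (ROH missing)
#' @export
low_het_roh_rule <- function(het_z, roh_z) {
  review <- !is.na(het_z) & het_z < -3 & is.na(roh_z)
  fail <- !is.na(het_z) & het_z < -3 & !is.na(roh_z) & roh_z < 2
  data.frame(fail_hom_low = fail, review = review)
}

# window pass indicator for the ROH scan: at most max_het heterozygous and
# max_missing missing calls per window of `window` SNPs
roh_window_pass <- function(g, window, max_het, max_missing) {
  n <- length(g)
  if (n < window) return(logical(0))
  het <- as.integer(!is.na(g) & g == 1L)
  mis <- as.integer(is.na(g))
  ch <- cumsum(het); cm <- cumsum(mis)
  i <- seq_len(n - window + 1)
  hw <- ch[i + window - 1] - c(0, ch)[i]
  mw <- cm[i + window - 1] - c(0, cm)[i]
  hw <= max_het & mw <= max_missing
}

#' Detect runs of homozygosity
#'
#' Sliding-window scan: a SNP is ROH-eligible if it lies in at least one
#' window of `window_snps` consecutive SNPs containing at most `max_het`
#' heterozygous and `max_missing` missing calls. Maximal runs of eligible
#' SNPs are split at inter-SNP gaps above `max_gap_kb` and reported when they
#' span at least `min_snps` SNPs and `min_length_kb` kb.
#'
#' @param calls genotype matrix (samples x variants) or `genotype_dataset`
#' @param variants variant map (`id`, `chrom`, `pos`); taken from the dataset
#'   when omitted
#' @param min_length_kb minimum segment length (default 1000 kb)
#' @param window_snps,max_het,max_missing,min_snps,max_gap_kb scan parameters
#' @param autosomes_only drop chrX/chrY variants first
#' @return list with `segments` (sample, chrom, start, end, n_snps, kb) and
#'   `total_kb` per sample
#' @export
detect_roh <- function(calls, variants = NULL, min_length_kb = 1000,
                       window_snps = 50, max_het = 1, max_missing = 5,
                       min_snps = 50, max_gap_kb = 1000,
                       autosomes_only = TRUE) {
  if (inherits(calls, "genotype_dataset")) {
    variants <- calls$variants
    calls <- calls$calls
  }
  if (is.null(variants)) stop("variant map required")
  if (autosomes_only) {
    keep <- !(variants$chrom %in% c("X", "Y", "23", "24"))
    calls <- calls[, keep, drop = FALSE]
    variants <- variants[keep, , drop = FALSE]
  }
  ids <- rownames(calls)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(calls)))
  segs <- list()
  total <- stats::setNames(numeric(nrow(calls)), ids)
  for (ch in unique(variants$chrom)) {
    vi <- which(variants$chrom == ch)
    if (length(vi) < 50) {
      warning("chromosome ", ch, " has fewer than 50 variants; skipped")
      next
    }
    pos <- variants$pos[vi]
    for (s in seq_len(nrow(calls))) {
      g <- calls[s, vi]
      wp <- roh_window_pass(g, window_snps, max_het, max_missing)
      if (!length(wp) || !any(wp)) next
      # SNP eligible iff covered by a passing window
      elig <- logical(length(g))
      for (w in which(wp)) elig[w:(w + window_snps - 1)] <- TRUE
      # split runs at large physical gaps
      brk <- c(FALSE, diff(pos) > max_gap_kb * 1000)
      run_id <- cumsum(!elig | brk)
      for (rid in unique(run_id[elig])) {
        i <- which(elig & run_id == rid)
        if (length(i) < min_snps) next
        kb <- (pos[max(i)] - pos[min(i)]) / 1000
        if (kb < min_length_kb) next
        segs[[length(segs) + 1]] <- data.frame(
          sample_id = ids[s], chrom = ch, start = pos[min(i)],
          end = pos[max(i)], n_snps = length(i), kb = kb,
          stringsAsFactors = FALSE)
        total[s] <- total[s] + kb
      }
    }
  }
  segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(sample_id = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0), n_snps = integer(0),
               kb = numeric(0))
  list(segments = segments, total_kb = total)
}

#' Infer genetic sex from chrX heterozygosity F and chrY/chrX intensity ratio
#'
#' Genetically male and female samples form two well-separated clusters in
#' the (F, ratio) plane; a 2-component Gaussian mixture is fitted and the
#' decision thresholds are the midpoints between cluster means. Phenotypic
#' males with appreciable chrX heterozygosity (F below `xxy_f_max`) and a
#' depressed ratio are called XXY-like.
#'
#' @param chrx_f per-sample chrX heterozygosity F-statistics
#' @param yx_ratio per-sample chrY/chrX probe intensity ratios
#' @param reported_sex `"M"`/`"F"` from the manifest
#' @param xxy_f_max F threshold for "non-negligible chrX heterozygosity" in
#'   males (default 0.8)
#' @param xxy_f_min lower F bound of the XXY band; reported males below it
#'   are treated as potential sample mix-ups, not XXY (default 0.2)
#' @return data.frame with `genetic_sex` (`"M"`, `"F"`, or `NA`), `call`
#'   (`XY`, `XX`, `XXY_like`, `sex_mismatch`, `unresolved`) and the fitted
#'   thresholds as attributes
#' @export
infer_sex <- function(chrx_f, yx_ratio, reported_sex, xxy_f_max = 0.8,
                      xxy_f_min = 0.2) {
  ok <- !is.na(chrx_f) & !is.na(yx_ratio)
  fit <- mclust::Mclust(cbind(chrx_f[ok], yx_ratio[ok]), G = 2,
                        verbose = FALSE)
  mu <- fit$parameters$mean                      # 2 x 2, columns = clusters
  male_cl <- which.max(mu[1, ])
  thr_f <- mean(mu[1, ]); thr_r <- mean(mu[2, ])
  n <- length(chrx_f)
  genetic <- rep(NA_character_, n)
  call <- rep("unresolved", n)
  for (i in seq_len(n)) {
    if (is.na(chrx_f[i]) || is.na(yx_ratio[i])) next
    hi_f <- chrx_f[i] > thr_f; hi_r <- yx_ratio[i] > thr_r
    if (hi_f && hi_r) genetic[i] <- "M"
    else if (!hi_f && !hi_r) genetic[i] <- "F"
    if (!is.na(reported_sex[i]) && reported_sex[i] == "M" &&
        chrx_f[i] < xxy_f_max && chrx_f[i] > xxy_f_min) {
      # phenotypic male with appreciable (but not female-level) chrX
      # heterozygosity; F near 0 in a reported male is a sample mix-up, not
      # an extra X
      call[i] <- "XXY_like"
    } else if (!is.na(genetic[i])) {
      if (is.na(reported_sex[i])) call[i] <- "unresolved"
      else if (genetic[i] == reported_sex[i])
        call[i] <- if (genetic[i] == "M") "XY" else "XX"
      else call[i] <- "sex_mismatch"
    }
  }
  out <- data.frame(genetic_sex = genetic, call = call,
                    stringsAsFactors = FALSE)
  attr(out, "thresholds") <- c(f = thr_f, ratio = thr_r)
  out
}

#' Classify chromosome-X aneuploidy from LRR and BAF
#'
#' Screens female-manifest samples whose mean chrX log R ratio lies more
#' than 3 robust SDs (median/MAD) from the female centre, or whose
#' heterozygous-probe B-allele-frequency band is clearly displaced from 0.5;
#' the BAF band then resolves the karyotype: no het band = XO (Turner); het
#' band consistently displaced = XO mosaic (low LRR) ; band modes near 1/3
#' and 2/3 = XXX (high LRR); displaced band without the trisomy modes at
#' high LRR = X structural change. Screen-positive samples with a normal
#' band are reported as intensity outliers (`none`), not aneuploid.
#'
#' @param chrx_lrr per-sample mean chrX LRR
#' @param baf_het list of per-sample BAF values at heterozygous chrX probes
#' @param sex reported sex; only `"F"` samples are screened
#' @param lrr_z_threshold screen threshold (default 3)
#' @param min_baf_probes minimum informative probes (default 30)
#' @param baf_dev_threshold median |BAF - 0.5| above which the het band is
#'   called displaced (default 0.08)
#' @return data.frame with `lrr_z`, `call` (`none`, `XO`, `XO_mosaic`, `XXX`,
#'   `X_structural`, `unresolved`) and `baf_dev`
#' @export
classify_x_aneuploidy <- function(chrx_lrr, baf_het, sex,
                                  lrr_z_threshold = 3, min_baf_probes = 30,
                                  baf_dev_threshold = 0.08) {
  fem <- !is.na(sex) & sex == "F"
  # robust location/scale: the aneuploid samples themselves would otherwise
  # inflate the screen SD in small cohorts
  mu <- stats::median(chrx_lrr[fem], na.rm = TRUE)
  sd_f <- stats::mad(chrx_lrr[fem], na.rm = TRUE)
  n <- length(chrx_lrr)
  z <- (chrx_lrr - mu) / sd_f
  call <- rep("none", n)
  dev <- rep(NA_real_, n)
  for (i in which(fem)) {
    if (is.na(z[i])) next
    baf <- baf_het[[i]]
    if (length(baf) >= min_baf_probes)
      dev[i] <- stats::median(abs(baf - 0.5))
    screened <- abs(z[i]) > lrr_z_threshold
    # a clearly displaced het band is direct evidence of allelic imbalance
    # and warrants examination even when the LRR screen narrowly misses
    displaced <- !is.na(dev[i]) && dev[i] > baf_dev_threshold
    if (!screened && !displaced) next
    if (length(baf) == 0 && screened && z[i] < 0) { call[i] <- "XO"; next }
    if (length(baf) < min_baf_probes) { call[i] <- "unresolved"; next }
    if (!displaced) { call[i] <- "none"; next }  # intensity outlier, euploid BAF
    if (!screened && abs(z[i]) < 1) { call[i] <- "unresolved"; next }
    if (z[i] < 0) call[i] <- "XO_mosaic"
    else {
      # XXX: two-mode fit closer to (1/3, 2/3) than to 0.5
      lo <- baf[baf < 0.5]; hi <- baf[baf >= 0.5]
      third_fit <- length(lo) && length(hi) &&
        abs(stats::median(lo) - 1 / 3) < abs(stats::median(lo) - 0.5) &&
        abs(stats::median(hi) - 2 / 3) < abs(stats::median(hi) - 0.5)
      call[i] <- if (third_fit) "XXX" else "X_structural"
    }
  }
  data.frame(lrr_z = z, call = call, baf_dev = dev, stringsAsFactors = FALSE)
}

# well label "A1".."H12" -> (row, col)
parse_well <- function(well) {
  cbind(row = match(substr(well, 1, 1), LETTERS),
        col = as.integer(substring(well, 2)))
}

#' Detect 180-degree plate rotation from sex-informative mismatches
#'
#' Compares the count of reported-vs-inferred sex mismatches under the
#' identity layout and under a 180-degree rotation of the plate
#' (well (r, c) mapped to (R+1-r, C+1-c)). A plate is declared rotated only
#' when the rotation removes all mismatches and the identity layout has at
#' least `min_mismatches`; unexplained mismatch clusters leave the plate
#' unresolved, to be excluded wholesale as a linkage error.
#'
#' @param plate_layout data.frame with `sample_id`, `plate`, `well`
#' @param reported_sex,inferred_sex named by sample id or aligned with
#'   `plate_layout`
#' @param nrow_plate,ncol_plate plate dimensions (default 8 x 12)
#' @param min_mismatches identity-layout mismatches required before a
#'   rotation is considered (default 2)
#' @return data.frame per plate: `plate`, `n_mismatch`,
#'   `n_mismatch_rotated`, `status` (`ok`, `rotated_180`, `unresolved`)
#' @export
detect_plate_orientation_errors <- function(plate_layout, reported_sex,
                                            inferred_sex, nrow_plate = 8,
                                            ncol_plate = 12,
                                            min_mismatches = 2) {
  pl <- plate_layout
  pl$reported <- reported_sex
  pl$inferred <- inferred_sex
  out <- list()
  for (p in sort(unique(pl$plate))) {
    sub <- pl[pl$plate == p, , drop = FALSE]
    rc <- parse_well(sub$well)
    informative <- !is.na(sub$reported) & !is.na(sub$inferred)
    mism <- sum(informative & sub$reported != sub$inferred)
    # rotation: the sample recorded at (r,c) was actually assayed at the
    # rotated well, so compare reported sex at (r,c) with inferred sex at
    # (R+1-r, C+1-c)
    rot_key <- paste(nrow_plate + 1 - rc[, "row"], ncol_plate + 1 - rc[, "col"])
    idx <- match(rot_key, paste(rc[, "row"], rc[, "col"]))
    both <- !is.na(idx) & !is.na(sub$reported) & !is.na(sub$inferred[idx])
    mism_rot <- sum(both & sub$reported != sub$inferred[idx])
    status <- if (mism == 0) "ok"
      else if (mism >= min_mismatches && mism_rot == 0) "rotated_180"
      else "unresolved"
    out[[length(out) + 1]] <- data.frame(plate = p, n_mismatch = mism,
                                         n_mismatch_rotated = mism_rot,
                                         status = status)
  }
  do.call(rbind, out)
}

#' Flag ancestry outliers by projection onto reference-panel PCs
#'
#' Cohort samples are projected onto principal components derived from an
#' external reference panel; samples further than `sd_threshold` SDs from
#' the cohort-wide mean on any of the first `n_pcs` PCs are flagged.
#'
#' @param calls cohort genotype matrix over the shared LD-pruned variant set
#' @param reference_pca a [run_pca()] result on the reference panel over the
#'   same variants
#' @param n_pcs PCs screened (default 10)
#' @param sd_threshold flag threshold in cohort SD units (default 10)
#' @return data.frame with `flag` and `max_abs_z`
#' @export
ancestry_outliers <- function(calls, reference_pca, n_pcs = 10,
                              sd_threshold = 10) {
  m <- ncol(calls)
  if (m < 1000) stop("only ", m, " shared variants; at least 1000 required")
  if (m < 10000) warning("only ", m, " shared variants; projection may be noisy")
  sc <- project_samples(reference_pca, calls)
  n_pcs <- min(n_pcs, ncol(sc))
  z <- scale(sc[, seq_len(n_pcs), drop = FALSE])
  maxz <- apply(abs(z), 1, max)
  data.frame(flag = maxz > sd_threshold, max_abs_z = maxz)
}

#' Discover duplicate samples
#'
#' Pairs with PI_HAT above the threshold on a thinned variant set are
#' reported; expected duplicates (from intentional-duplicate manifest
#' positions) are confirmed, unexpected ones are classified from manifest
#' identity fields, and in each pair the copy with the lower call rate is
#' marked for exclusion. A missing expected duplicate raises a
#' plate-tracking warning.
#'
#' @param calls genotype matrix (thinned, e.g. MAF > 0.05) with sample-id
#'   rownames
#' @param expected data.frame of expected duplicate pairs (`id1`, `id2`),
#'   or `NULL`
#' @param threshold PI_HAT threshold (default 0.95)
#' @param call_rates named per-sample call rates (default computed)
#' @return data.frame per detected pair: ids, `pi_hat`, `expected`,
#'   `exclude` (the lower-call-rate member)
#' @export
find_duplicates <- function(calls, expected = NULL, threshold = 0.95,
                            call_rates = NULL) {
  if (inherits(calls, "genotype_dataset")) calls <- calls$calls
  if (is.null(call_rates))
    call_rates <- stats::setNames(rowMeans(!is.na(calls)), rownames(calls))
  ib <- ibd_pairs(calls)
  hits <- ib[ib$pi_hat > threshold, , drop = FALSE]
  pkey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  hits$expected <- FALSE
  if (!is.null(expected) && nrow(expected)) {
    ek <- pkey(expected$id1, expected$id2)
    hits$expected <- pkey(hits$id1, hits$id2) %in% ek
    missing <- !(ek %in% pkey(hits$id1, hits$id2))
    if (any(missing))
      warning("plate-tracking alert: expected duplicate pair(s) not found: ",
              paste(ek[missing], collapse = "; "))
  }
  hits$exclude <- ifelse(call_rates[hits$id1] <= call_rates[hits$id2],
                         hits$id1, hits$id2)
  hits[, c("id1", "id2", "pi_hat", "expected", "exclude")]
}

SAMPLE_STATUS_ORDER <- c("fail_initial", "fail_callrate", "fail_het_high",
                         "fail_hom_low", "fail_sex_mismatch", "fail_linkage",
                         "fail_aneuploidy", "fail_ancestry", "fail_consent")

#' Compile the consolidated per-sample QC report
#'
#' One row per sample with a single primary status (the first failed
#' criterion in ledger order) plus one evidence flag column per criterion;
#' samples may fail several criteria at once. Pass + failure counts
#' (deduplicated) reconcile to the total.
#'
#' @param sample_ids character vector
#' @param flags named list of logical vectors (names from
#'   `fail_initial`, `fail_callrate`, `fail_het_high`, `fail_hom_low`,
#'   `fail_sex_mismatch`, `fail_linkage`, `fail_aneuploidy`,
#'   `fail_ancestry`, `fail_consent`), each aligned with `sample_ids`
#' @return data.frame with `sample_id`, `status`, per-criterion flag columns;
#'   category counts in attribute `counts`
#' @export
compile_sample_report <- function(sample_ids, flags = list()) {
  n <- length(sample_ids)
  unknown <- setdiff(names(flags), SAMPLE_STATUS_ORDER)
  if (length(unknown)) stop("unknown flag categories: ",
                            paste(unknown, collapse = ", "))
  out <- data.frame(sample_id = sample_ids, status = "pass",
                    stringsAsFactors = FALSE)
  for (nm in SAMPLE_STATUS_ORDER) {
    v <- if (nm %in% names(flags)) rep_len(flags[[nm]], n) else rep(FALSE, n)
    v[is.na(v)] <- FALSE
    out[[nm]] <- v
  }
  for (nm in rev(SAMPLE_STATUS_ORDER)) out$status[out[[nm]]] <- nm
  counts <- c(table(factor(out$status, levels = c("pass", SAMPLE_STATUS_ORDER))))
  attr(out, "counts") <- counts
  out
}
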