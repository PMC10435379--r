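test_that("initial plate QC applies the sample and plate thresholds", {
  sm <- data.frame(
    sample_id = sprintf("s%02d", 1:8),
    plate = c(1, 1, 1, 1, 2, 2, 2, 2),
    dqc = c(0.80, 0.99, 0.99, 0.99, 0.95, 0.95, 0.95, 0.95),
    qc_callrate = c(0.99, 0.999, 0.999, 0.999, 0.96, 0.999, 0.999, 0.999))
  res <- initial_plate_qc(sm)
  expect_setequal(res$excluded_samples$sample_id, c("s01", "s05"))
  expect_equal(res$excluded_samples$reason[res$excluded_samples$sample_id == "s01"],
               "low_dqc")
  clean <- initial_plate_qc(data.frame(sample_id = "a", plate = 1, dqc = 0.99,
                                       qc_callrate = 0.999))
  expect_equal(nrow(clean$excluded_samples), 0)
  expect_length(clean$excluded_plates, 0)
  # plate mean call rate among survivors below 98.5% drops the plate
  low <- data.frame(sample_id = paste0("x", 1:4), plate = 9, dqc = 0.95,
                    qc_callrate = c(0.975, 0.98, 0.982, 0.984))
  expect_equal(initial_plate_qc(low)$excluded_plates, 9)
  # 96-well plate with 6 failing samples: 93.75% pass rate, flagged
  big <- data.frame(sample_id = paste0("y", 1:96), plate = 3, dqc = 0.95,
                    qc_callrate = c(rep(0.90, 6), rep(0.999, 90)))
  expect_true(3 %in% initial_plate_qc(big)$flagged_plates)
  expect_false(3 %in% initial_plate_qc(big)$excluded_plates)
})

test_that("plate-effect p-values are uniform under the null", {
  set.seed(20)
  n_plate <- 4; per <- 48
  plate <- rep(1:n_plate, each = per)
  region <- rep(rep(c("N", "S"), each = per / 2), n_plate)
  m <- 400
  p <- runif(m, 0.1, 0.5)
  calls <- matrix(rbinom(n_plate * per * m, 2, rep(p, each = n_plate * per)),
                  n_plate * per, m)
  res <- plate_effect_test(calls, plate, region)
  pv <- as.vector(res$p)
  pv <- pv[!is.na(pv)]
  expect_gt(suppressWarnings(ks.test(pv, "punif"))$p.value, 0.01)
  expect_lt(min(pv), 1)   # sanity: p-values actually computed
})

test_that("monomorphic variants are flagged rather than tested", {
  calls <- cbind(rep(2L, 40), rbinom(40, 2, 0.4))
  res <- plate_effect_test(calls, rep(1:2, each = 20), rep("r", 40))
  expect_true(all(res$flags[, 1] == "monomorphic"))
  expect_true(all(is.na(res$p[, 1])))
  expect_true(all(!is.na(res$p[, 2])))
})

test_that("a planted het-to-hom plate artifact is detected with huge significance", {
  set.seed(21)
  n_plate <- 10; per <- 96
  plate <- rep(1:n_plate, each = per)
  region <- rep(rep(c("N", "S"), each = per / 2), n_plate)
  g <- rbinom(n_plate * per, 2, 0.3)
  bad <- plate == 3 & g == 1
  g[bad & runif(length(g)) < 0.5] <- 2L      # delta = 0.5 miscalls on plate 3
  res <- plate_effect_test(matrix(g, ncol = 1), plate, region)
  expect_lt(min(res$p, na.rm = TRUE), 1e-8)
  expect_equal(unname(which.min(res$p[, 1])), 3)
  # the additive dosage encoding is far less sensitive to this artifact
  dos <- plate_effect_test(matrix(g, ncol = 1), plate, region,
                           encoding = "dosage")
  expect_gt(min(dos$p, na.rm = TRUE), min(res$p, na.rm = TRUE))
})

test_that("plate fail rules fire exactly as stated", {
  r1 <- apply_plate_fail_rules(c(1e-11, 0.5, 0.3))
  expect_true(r1$fail); expect_match(r1$reason, "1e-10")
  r2 <- apply_plate_fail_rules(c(5e-5, 5e-5, 5e-5, 5e-5, 0.2))
  expect_true(r2$fail); expect_match(r2$reason, "1e-4")
  r2b <- apply_plate_fail_rules(c(5e-5, 5e-5, 5e-5, 0.2))  # only 3 instances
  expect_false(r2b$fail)
  r3 <- apply_plate_fail_rules(1e-9, fld = 7, hetso = 0.5, homro = 3.0)
  expect_true(r3$fail); expect_match(r3$reason, "clustering")
  r4 <- apply_plate_fail_rules(1e-9, fld = 9, hetso = 0.5, homro = 3.0)
  expect_false(r4$fail); expect_true(r4$review)
  r5 <- apply_plate_fail_rules(1e-9)                        # metrics missing
  expect_false(r5$fail); expect_true(r5$review)
  r6 <- apply_plate_fail_rules(1e-6, fld = 20, hetso = 2, homro = 5)
  expect_false(r6$fail); expect_true(r6$review)             # 2e-5 band
  r7 <- apply_plate_fail_rules(0.2)
  expect_false(r7$fail); expect_false(r7$review)
})

test_that("batch fail rules respect the array-version limit", {
  v1 <- apply_batch_fail_rules(c(1e-5, 1e-5, 1e-5, 0.5), array_version = 1)
  expect_true(v1$fail)
  v2 <- apply_batch_fail_rules(c(1e-5, 1e-5, 1e-5, 0.5), array_version = 2)
  expect_false(v2$fail)
  expect_true(apply_batch_fail_rules(c(1e-11, 1), 2)$fail)
  expect_true(apply_batch_fail_rules(c(5e-4, 1), 1)$review)
})

test_that("batch-effect scan fails a planted batch shift and spares the null", {
  set.seed(22)
  n <- 480
  batch <- rep(1:5, each = 96)
  region <- rep(rep(c("N", "S"), each = 48), 5)
  m <- 60
  p <- runif(m, 0.2, 0.5)
  calls <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  # plant a strong miscall shift in batch 2 for variant 1
  bad <- batch == 2 & calls[, 1] == 1
  calls[bad & runif(n) < 0.8, 1] <- 2L
  res <- batch_effect_test(calls, batch, region, unrelated_mask = rep(TRUE, n),
                           array_version = 1)
  expect_true(res$fail[1])
  expect_lt(mean(res$fail[-1]), 0.05)
})

test_that("region-stratified HWE matches hand-computed counts", {
  # exact HWE proportions: chi-square 0, p = 1
  g <- rep(c(0L, 1L, 2L), c(360, 480, 160))
  r <- hwe_region_test(g, rep("one", 1000))
  expect_equal(r$stat, 0)
  expect_equal(r$p, 1)
  # (50, 0, 50): p-hat = 0.5, chi-square = 100
  g2 <- rep(c(0L, 2L), c(50, 50))
  r2 <- hwe_region_test(g2, rep("one", 100))
  expect_equal(r2$stat, 100)
  expect_true(r2$fail)
})

test_that("HWE statistic equals the brute-force oracle on random instances", {
  set.seed(23)
  for (k in 1:20) {
    nr <- sample(2:10, 1)
    region <- sample(letters[1:nr], 300, replace = TRUE)
    g <- rbinom(300, 2, runif(1, 0.05, 0.95))
    g[sample(300, 10)] <- NA
    mine <- hwe_region_test(g, region)
    orc <- oracle_hwe(g, region)
    expect_equal(mine$stat, orc$stat, tolerance = 1e-12)
    expect_equal(mine$df, orc$df)
    expect_equal(mine$p, orc$p, tolerance = 1e-12)
  }
})

test_that("the summed HWE statistic is chi-square with one df per region", {
  set.seed(24)
  m <- 1500
  region <- rep(letters[1:10], each = 60)
  p <- runif(m, 0.2, 0.8)
  calls <- matrix(rbinom(600 * m, 2, rep(p, each = 600)), 600, m)
  r <- hwe_region_test(calls, region)
  expect_true(all(r$df == 10))
  expect_lt(abs(mean(r$stat) - 10), 4 * sqrt(2 * 10 / m))
})

test_that("chrX HWE uses females only and small regions reduce the df", {
  set.seed(25)
  sex <- rep(c("M", "F"), 100)
  g <- ifelse(sex == "M", sample(c(0L, 2L), 200, TRUE), rbinom(200, 2, 0.5))
  rX <- hwe_region_test(g, rep("one", 200), sex = sex, chromosome = "X")
  orc <- oracle_hwe(g[sex == "F"], rep("one", 100))
  expect_equal(rX$stat, orc$stat)
  expect_error(hwe_region_test(g, rep("one", 200), chromosome = "X"), "sex")
  tiny <- hwe_region_test(c(0L, 1L, 2L, 1L, 1L), c("a", "a", "a", "a", "b"))
  expect_equal(tiny$df, 1)  # region b has < 2 samples
})

test_that("reference MAF concordance handles flips, swaps and the 0.2 rule", {
  ref <- data.frame(chrom = "1", pos = c(100, 200, 300, 400, 500, 500),
                    a1 = c("A", "T", "T", "T", "G", "G"),
                    a2 = c("G", "C", "C", "A", "A", "T"),
                    af = c(0.35, 0.10, 0.20, 0.50, 0.4, 0.2))
  d <- data.frame(chrom = "1",
                  pos = c(100, 200, 300, 600, 500, 400),
                  a1 = c("A", "T", "A", "A", "G", "A"),
                  a2 = c("G", "C", "G", "G", "A", "T"),
                  af = c(0.30, 0.45, 0.20, 0.10, 0.3, 0.2))
  res <- reference_maf_filter(d, ref)
  expect_equal(res$status[1], "keep")              # |0.30 - 0.35| <= 0.2
  expect_equal(res$status[2], "drop_maf")          # 0.45 vs 0.10
  expect_equal(res$status[3], "keep")              # A/G at 0.2 vs T/C: strand flip
  expect_equal(res$orientation[3], "flip")
  expect_equal(res$status[4], "no_reference")
  expect_equal(res$status[5], "drop_multiallelic")
  expect_equal(res$status[6], "drop_ambiguous")    # A/T pair, ref MAF 0.5
})

test_that("strand-ambiguous variants pass only when both MAFs are low", {
  ref <- data.frame(chrom = "1", pos = 10, a1 = "A", a2 = "T", af = 0.2)
  d <- data.frame(chrom = "1", pos = 10, a1 = "A", a2 = "T", af = 0.25)
  expect_equal(reference_maf_filter(d, ref)$status, "keep")
  d$af <- 0.45
  expect_equal(reference_maf_filter(d, ref)$status, "drop_ambiguous")
})

test_that("duplicate probesets retain the higher call rate with logged ties", {
  ps <- data.frame(variant_id = c("v1", "v1", "v2", "v3", "v3"),
                   probeset = c("AX-2", "AX-1", "AX-3", "AX-5", "AX-4"),
                   call_rate = c(0.99, 0.97, 0.95, 0.98, 0.98))
  res <- resolve_duplicate_probesets(ps)
  expect_true(res$retained[res$probeset == "AX-2"])
  expect_false(res$retained[res$probeset == "AX-1"])
  expect_true(res$retained[res$probeset == "AX-3"])
  expect_true(res$retained[res$probeset == "AX-4"])   # lexicographic tie-break
  expect_false(res$retained[res$probeset == "AX-5"])
  expect_equal(attr(res, "ties"), "v3")
})

test_that("the variant report is idempotent with one primary status per variant", {
  v <- data.frame(id = paste0("v", 1:5))
  rep1 <- compile_variant_report(v,
                                 plate_fail = c(TRUE, FALSE, FALSE, FALSE, FALSE),
                                 hwe_fail = c(TRUE, TRUE, FALSE, FALSE, FALSE),
                                 callrate_fail = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(rep1$status,
               c("fail_plate", "fail_hwe", "fail_callrate", "pass", "pass"))
  rep2 <- compile_variant_report(v,
                                 plate_fail = rep1$status == "fail_plate",
                                 hwe_fail = c(TRUE, TRUE, FALSE, FALSE, FALSE),
                                 callrate_fail = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_identical(rep1, rep2)
})
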