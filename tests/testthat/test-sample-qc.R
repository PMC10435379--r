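test_that("heterozygosity outliers are judged within region, not globally", {
  het <- rep(0.30, 50)
  z <- heterozygosity_outliers(het, rep("a", 50))
  expect_true(all(z$z == 0))
  expect_false(any(z$fail_het_high))
  # north/south gradient: +3.5 SD within region but only ~+1 SD globally
  set.seed(30)
  north <- rnorm(200, 0.32, 0.004)
  south <- rnorm(200, 0.27, 0.004)
  south[1] <- 0.27 + 3.5 * 0.004
  het2 <- c(north, south)
  region <- rep(c("N", "S"), each = 200)
  res <- heterozygosity_outliers(het2, region)
  expect_true(res$fail_het_high[201])
  global_z <- (het2[201] - mean(het2)) / sd(het2)
  expect_lt(global_z, 2)
  expect_warning(heterozygosity_outliers(rep(0.3, 5), rep("tiny", 5)), "tiny")
})

test_that("a simulated 1:1 DNA mixture is flagged for excess heterozygosity", {
  set.seed(31)
  flagged <- replicate(50, {
    p <- runif(1500, 0.1, 0.9)
    n <- 80
    g <- matrix(rbinom(n * 1500, 2, rep(p, each = n)), n, 1500)
    # contaminate sample 1: mixture of two genomes, hets called wherever
    # the two donors differ
    donor <- rbinom(1500, 2, p)
    mixed <- ifelse(g[1, ] == donor, g[1, ], 1L)
    g[1, ] <- mixed
    het <- rowMeans(g == 1L)
    heterozygosity_outliers(het, rep("r", n), min_region_n = 20)$fail_het_high[1]
  })
  expect_gte(mean(flagged), 0.95)
})

test_that("low heterozygosity is excused only by extensive homozygosity runs", {
  res <- low_het_roh_rule(c(-3.5, -3.5, -1.0, 3.2), c(3.0, 0.1, 0.1, 0.1))
  expect_equal(res$fail_hom_low, c(FALSE, TRUE, FALSE, FALSE))
  miss <- low_het_roh_rule(-3.5, NA)
  expect_false(miss$fail_hom_low)
  expect_true(miss$review)
})

test_that("ROH detection matches the brute-force scan oracle", {
  set.seed(32)
  for (k in 1:6) {
    m <- 1200
    pos <- sort(sample.int(2e8, m))
    p <- runif(m, 0.05, 0.5)
    g <- rbinom(m, 2, p)
    # plant a long homozygous stretch in half the instances
    if (k %% 2 == 0) {
      i <- 300:550
      g[i] <- ifelse(rbinom(length(i), 1, p[i]) > 0, 2L, 0L)
    }
    g[sample(m, 20)] <- NA
    v <- data.frame(id = paste0("v", 1:m), chrom = "1", pos = pos)
    mine <- detect_roh(matrix(g, 1), v, autosomes_only = FALSE)
    expect_equal(unname(mine$total_kb), oracle_roh_total(g, pos),
                 tolerance = 1e-9, label = paste("instance", k))
  }
})

test_that("a planted homozygous segment is recovered with tight boundaries", {
  set.seed(33)
  m <- 3000
  pos <- sort(sample.int(1e8, m))          # ~33 kb spacing
  p <- runif(m, 0.2, 0.8)
  g <- rbinom(m, 2, p)
  seg <- which(pos >= 4e7 & pos <= 4.5e7)  # 5 Mbp autozygous segment
  g[seg] <- ifelse(rbinom(length(seg), 1, p[seg]) > 0, 2L, 0L)
  v <- data.frame(id = paste0("v", 1:m), chrom = "1", pos = pos)
  res <- detect_roh(matrix(g, 1), v, autosomes_only = FALSE)
  expect_gte(nrow(res$segments), 1)
  big <- res$segments[which.max(res$segments$kb), ]
  spacing2 <- 2 * 1e8 / m
  expect_lt(abs(big$start - 4e7), 40 * spacing2)
  expect_lt(abs(big$end - 4.5e7), 40 * spacing2)
  # a fully heterozygous sample has no runs
  none <- detect_roh(matrix(rep(1L, m), 1), v, autosomes_only = FALSE)
  expect_equal(nrow(none$segments), 0)
  expect_equal(unname(none$total_kb), 0)
})

test_that("offspring of first cousins carry about 1/16 of the genome in ROH", {
  set.seed(34)
  n_off <- 100
  m <- 3000
  v <- data.frame(id = paste0("v", 1:m),
                  chrom = rep(c("1", "2"), each = m / 2),
                  pos = rep(sort(sample.int(1e8, m / 2)), 2))
  v <- v[order(v$chrom, v$pos), ]
  map <- uniform_genetic_map(c("1", "2"))
  p <- runif(m, 0.2, 0.8)
  fracs <- replicate(n_off, {
    founder <- function() rbind(rbinom(m, 1, p), rbinom(m, 1, p))
    gf <- founder(); gm <- founder()
    s1 <- drop_gametes(gf, gm, v, map, haplotypes = TRUE)
    s2 <- drop_gametes(gf, gm, v, map, haplotypes = TRUE)
    p1 <- drop_gametes(s1, founder(), v, map, haplotypes = TRUE)
    p2 <- drop_gametes(s2, founder(), v, map, haplotypes = TRUE)
    child <- drop_gametes(p1, p2, v, map)
    tot <- detect_roh(matrix(child, 1), v)$total_kb
    tot * 1000 / 2e8
  })
  expect_lt(abs(mean(fracs) - 1 / 16), 0.02)
})

test_that("sex inference separates the clusters and spots mismatches", {
  set.seed(35)
  n <- 150
  truth <- sample(c("M", "F"), n, replace = TRUE)
  f <- ifelse(truth == "M", rnorm(n, 0.98, 0.015), rnorm(n, 0.02, 0.04))
  r <- ifelse(truth == "M", rnorm(n, 1.0, 0.07), rnorm(n, 0.25, 0.05))
  reported <- truth
  reported[1:3] <- ifelse(truth[1:3] == "M", "F", "M")   # swapped records
  res <- infer_sex(f, r, reported)
  expect_true(all(res$call[1:3] == "sex_mismatch"))
  expect_true(all(res$call[-(1:3)] %in% c("XY", "XX")))
  expect_equal(res$genetic_sex[-(1:3)], truth[-(1:3)])
  # XXY-like: reported male, intermediate F and depressed ratio
  res2 <- infer_sex(c(f, 0.5), c(r, 0.65), c(reported, "M"))
  expect_equal(res2$call[n + 1], "XXY_like")
  # missing metric is unresolved
  res3 <- infer_sex(c(f, NA), c(r, 0.4), c(reported, "M"))
  expect_equal(res3$call[n + 1], "unresolved")
})

test_that("chrX karyotypes are recovered from LRR and BAF with no euploid calls", {
  sim <- simulate_cohort(sim_config(
    n_regions = 4, samples_per_region = 80,
    n_variants = 300, n_x_variants = 100,
    pedigree_spec = list(trios = 0, sib_pairs = 0, half_sib_pairs = 0,
                         parent_offspring_pairs = 0, consanguineous_pairs = 0,
                         first_cousin_offspring = 0),
    aneuploidy_counts = c(XO = 5, XO_mosaic = 5, XXX = 6, XXY = 5),
    duplicate_pairs = 0, n_migrants = 0, seed = 36))
  sm <- sim$sample_metrics
  kt <- sim$truth$karyotype[sm$sample_id]
  an <- classify_x_aneuploidy(sm$chrx_lrr, sm$baf_het, sm$sex)
  sx <- infer_sex(sm$chrx_f, sm$yx_ratio, sm$sex)
  pred <- ifelse(sx$call == "XXY_like", "XXY", an$call)
  planted <- kt %in% c("XO", "XO_mosaic", "XXX", "XXY")
  expect_gte(mean(pred[planted] == kt[planted]), 0.95)
  # euploid females under the 3-SD screen receive no karyotype call
  euploid_f <- kt == "XX" & abs(an$lrr_z) <= 3
  expect_true(all(an$call[euploid_f] == "none"))
})

test_that("180-degree plate rotations are traced and unexplained clusters flagged", {
  wells <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, 8))
  layout <- data.frame(sample_id = paste0("s", 1:96), plate = 1, well = wells)
  set.seed(37)
  truth <- sample(c("M", "F"), 96, replace = TRUE)
  # clean plate
  clean <- detect_plate_orientation_errors(layout, truth, truth)
  expect_equal(clean$status, "ok")
  # rotated plate: the DNA at each well belongs to the rotated position
  rot_of <- function(w) {
    r <- match(substr(w, 1, 1), LETTERS); c <- as.integer(substring(w, 2))
    paste0(LETTERS[9 - r], 13 - c)
  }
  inferred <- truth[match(rot_of(wells), wells)]
  expect_gte(sum(inferred != truth), 8)
  rot <- detect_plate_orientation_errors(layout, truth, inferred)
  expect_equal(rot$status, "rotated_180")
  expect_equal(rot$n_mismatch_rotated, 0)
  # three random swaps cannot be explained by rotation
  bad <- truth
  bad[c(2, 17, 40)] <- ifelse(truth[c(2, 17, 40)] == "M", "F", "M")
  un <- detect_plate_orientation_errors(layout, truth, bad)
  expect_equal(un$status, "unresolved")
})

test_that("no clean plate is ever declared rotated", {
  set.seed(38)
  wells <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, 8))
  statuses <- replicate(1000, {
    truth <- sample(c("M", "F"), 96, replace = TRUE)
    layout <- data.frame(sample_id = paste0("s", 1:96), plate = 1, well = wells)
    detect_plate_orientation_errors(layout, truth, truth)$status
  })
  expect_true(all(statuses == "ok"))
})

test_that("ancestry projection flags samples from a differentiated population", {
  set.seed(39)
  m <- 2000
  p0 <- runif(m, 0.1, 0.9)
  bn_freq <- function(f) if (f > 0)
    rbeta(m, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f) else p0
  draw <- function(p, n) matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  pA <- bn_freq(0.02); pB <- bn_freq(0.15)
  ref <- rbind(draw(pA, 120), draw(pB, 120))         # two reference ancestries
  rp <- run_pca(ref, n_pcs = 5)
  cohort <- draw(pA, 150)                            # same ancestry as ref pop A
  migrant <- draw(pB, 1)                             # from the distant ancestry
  expect_warning(
    res <- ancestry_outliers(rbind(cohort, migrant), rp, n_pcs = 5,
                             sd_threshold = 10),
    "noisy")   # below the 10k shared-variant comfort level
  expect_false(any(res$flag[1:150]))
  expect_true(res$flag[151])
  expect_identical(res$flag, res$max_abs_z > 10)     # rule boundary is exact
  expect_error(ancestry_outliers(cohort[, 1:500], rp), "1000")
})

test_that("duplicate discovery confirms expected pairs and drops the worse copy", {
  set.seed(40)
  p <- runif(3000, 0.1, 0.5)
  n <- 30
  g <- matrix(rbinom(n * 3000, 2, rep(p, each = n)), n, 3000)
  rownames(g) <- paste0("s", 1:n)
  g[2, ] <- g[1, ]                                    # exact duplicate
  err <- rbinom(3000, 1, 0.01) == 1                   # 1% discordance
  g[4, ] <- ifelse(err, (g[3, ] + 1L) %% 3L, g[3, ])
  g[2, sample(3000, 300)] <- NA                       # s2 has the lower call rate
  expected <- data.frame(id1 = "s1", id2 = "s2")
  res <- find_duplicates(g, expected = expected)
  key <- paste(pmin(res$id1, res$id2), pmax(res$id1, res$id2))
  expect_setequal(key, c("s1 s2", "s3 s4"))
  expect_true(res$expected[key == "s1 s2"])
  expect_false(res$expected[key == "s3 s4"])
  expect_gt(res$pi_hat[key == "s3 s4"], 0.97)
  expect_equal(res$exclude[key == "s1 s2"], "s2")
  # a missing expected duplicate raises a plate-tracking alert
  expect_warning(find_duplicates(g, expected = data.frame(id1 = "s9",
                                                          id2 = "s10")),
                 "plate-tracking")
})

test_that("the sample ledger keeps one primary status and conserves counts", {
  ids <- paste0("s", 1:6)
  rep1 <- compile_sample_report(ids, list(
    fail_het_high = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    fail_sex_mismatch = c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
    fail_ancestry = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)))
  expect_equal(rep1$status,
               c("pass", "fail_het_high", "fail_sex_mismatch", "fail_ancestry",
                 "pass", "pass"))
  # s2 failed two criteria: primary status is first in ledger order, both
  # evidence flags kept
  expect_true(rep1$fail_het_high[2] && rep1$fail_sex_mismatch[2])
  counts <- attr(rep1, "counts")
  expect_equal(sum(counts), length(ids))
  expect_error(compile_sample_report(ids, list(bogus = TRUE)), "unknown")
  all_pass <- compile_sample_report(ids)
  expect_true(all(all_pass$status == "pass"))
})
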