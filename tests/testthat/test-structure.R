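test_that("LD pruning keeps independent variants and removes correlated pairs", {
  set.seed(50)
  g <- matrix(rbinom(100 * 30, 2, 0.4), 100, 30)
  expect_equal(ld_prune(g), 1:30)              # independent draws survive
  g2 <- cbind(g[, 1], g[, 1], g[, 2])          # a perfectly correlated pair
  expect_equal(length(ld_prune(g2)), 2)
})

test_that("the pruned set has no within-window pair above the threshold", {
  set.seed(51)
  n <- 120; m <- 300
  base <- matrix(rbinom(n * m, 2, 0.3), n, m)
  # induce local correlation by copying neighbours with noise
  for (j in seq(2, m, by = 3)) {
    cp <- base[, j - 1]
    fl <- runif(n) < 0.1
    base[fl, j] <- rbinom(sum(fl), 2, 0.3)
    base[!fl, j] <- cp[!fl]
  }
  kept <- ld_prune(base, window_snps = 50, step_snps = 5, r2_threshold = 0.2)
  for (s in seq(1, length(kept), by = 7)) {
    w <- kept[kept >= kept[s] & kept < kept[s] + 50]
    if (length(w) < 2) next
    r2 <- suppressWarnings(cor(base[, w]))^2
    expect_true(all(r2[upper.tri(r2)] <= 0.2 + 1e-12))
  }
})

test_that("PCA separates differentiated populations on PC1", {
  set.seed(52)
  sim <- bn_two_pops(200, 5000, 0.01)
  pca <- run_pca(sim$g, n_pcs = 4)
  s1 <- pca$scores[, 1]
  thr <- mean(c(mean(s1[sim$pop == "A"]), mean(s1[sim$pop == "B"])))
  acc <- max(mean((s1 > thr) == (sim$pop == "B")),
             mean((s1 < thr) == (sim$pop == "B")))
  expect_gte(acc, 0.99)
  # score variance reproduces the eigenvalues
  expect_equal(apply(pca$scores, 2, var), pca$eigenvalues, tolerance = 1e-8)
  # permutation equivariance
  perm <- sample(nrow(sim$g))
  pca2 <- run_pca(sim$g[perm, ], n_pcs = 4)
  for (k in 1:4) {
    sgn <- sign(sum(pca$scores[perm, k] * pca2$scores[, k]))
    expect_equal(pca2$scores[, k], sgn * pca$scores[perm, k], tolerance = 1e-6)
  }
})

test_that("projection reproduces training scores and flags missingness", {
  set.seed(53)
  g <- matrix(rbinom(80 * 600, 2, 0.4), 80, 600)
  pca <- run_pca(g, n_pcs = 5)
  proj <- project_samples(pca, g)
  expect_equal(matrix(proj, nrow(proj)), matrix(pca$scores, nrow(proj)),
               tolerance = 1e-8)
  gna <- g[1:2, , drop = FALSE]
  gna[1, 1:400] <- NA
  expect_equal(attr(project_samples(pca, gna), "flagged"), 1L)
  expect_error(project_samples(pca, matrix(NA_integer_, 1, 600)), "missing")
})

test_that("BIC selects two informative PCs for three populations and none under permutation", {
  set.seed(54)
  # moderate differentiation: three clusters that overlap along any single
  # axis but separate in the PC1-PC2 plane, so exactly two PCs carry signal
  m <- 2000
  p0 <- runif(m, 0.1, 0.9)
  f <- 0.006
  pop_freq <- function() rbeta(m, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
  g <- do.call(rbind, lapply(1:3, function(k) {
    p <- pop_freq()
    matrix(rbinom(100 * m, 2, rep(p, each = 100)), 100, m)
  }))
  lab <- factor(rep(c("a", "b", "c"), each = 100))
  pca <- run_pca(g, n_pcs = 6)
  expect_equal(select_informative_pcs(pca$scores, lab, "multinomial")$k, 2)
  nulls <- replicate(20, select_informative_pcs(pca$scores, sample(lab),
                                                "multinomial")$k)
  expect_gte(mean(nulls == 0), 0.9)
  expect_equal(select_informative_pcs(pca$scores, factor(rep("a", 300)),
                                      "multinomial")$k, 0)
})

test_that("HMM posteriors equal brute-force path enumeration", {
  set.seed(55)
  for (k in 1:15) {
    n <- sample(3:12, 1)
    e_in <- runif(n, 0.01, 0.99)
    emis <- cbind(1 - e_in, e_in)
    d <- runif(n - 1, 0.01, 5)
    rho <- runif(1, 0.3, 2); pi_in <- runif(1, 0.02, 0.3)
    mine <- qcpop:::hmm_posterior(emis, d, rho = rho, pi_in = pi_in)
    orc <- oracle_hmm_posterior(emis, d, rho = rho, pi_in = pi_in)
    expect_equal(mine, orc, tolerance = 1e-12)
  }
})

make_loading_track <- function(m = 1500, block = NULL, inflate = 10,
                               chrom = "1") {
  pos <- sort(sample.int(1e8, m))
  z <- rnorm(m)
  if (!is.null(block)) {
    j <- pos >= block[1] & pos <= block[2]
    z[j] <- rnorm(sum(j), 0, sqrt(inflate))
  }
  list(variants = data.frame(id = paste0("v", 1:m), chrom = chrom, pos = pos),
       loadings = z)
}

test_that("the loading HMM recovers a planted block and stays quiet on the null", {
  set.seed(56)
  map <- uniform_genetic_map("1")
  jacc <- replicate(20, {
    tr <- make_loading_track(block = c(3e7, 3.2e7))
    reg <- detect_lrld_hmm(tr$loadings, tr$variants, map)
    if (nrow(reg) == 0) return(0)
    inter <- sum(pmax(0, pmin(reg$end, 3.2e7) - pmax(reg$start, 3e7)))
    union <- sum(reg$end - reg$start) + 2e6 - inter
    inter / union
  })
  expect_gte(mean(jacc), 0.8)
  nulls <- replicate(30, {
    tr <- make_loading_track()
    nrow(detect_lrld_hmm(tr$loadings, tr$variants, map))
  })
  expect_gte(mean(nulls == 0), 0.9)
})

test_that("detected runs closer than 1 Mbp merge into one region", {
  set.seed(57)
  m <- 2000
  pos <- sort(sample.int(1e8, m))
  z <- rnorm(m)
  hot1 <- pos >= 3.0e7 & pos <= 3.1e7
  hot2 <- pos >= 3.15e7 & pos <= 3.25e7     # 0.5 Mbp gap to the first run
  z[hot1 | hot2] <- rnorm(sum(hot1 | hot2), 0, 6)
  v <- data.frame(id = paste0("v", 1:m), chrom = "1", pos = pos)
  reg <- detect_lrld_hmm(z, v, uniform_genetic_map("1"))
  expect_equal(nrow(reg), 1)
  expect_lt(reg$start, 3.05e7)
  expect_gt(reg$end, 3.2e7)
})

test_that("iterative PCA cleanup removes planted LRLD and then terminates", {
  set.seed(58)
  sim <- simulate_cohort(sim_config(
    n_regions = 4, samples_per_region = 80, n_variants = 1200,
    n_x_variants = 100,
    pedigree_spec = list(trios = 0, sib_pairs = 0, half_sib_pairs = 0,
                         parent_offspring_pairs = 0, consanguineous_pairs = 0,
                         first_cousin_offspring = 0),
    aneuploidy_counts = c(XO = 0, XO_mosaic = 0, XXX = 0, XXY = 0),
    # an inversion-like block: two ancestral haplotypes over 2.5 Mbp, large
    # enough to rank among the leading PCs as real LRLD regions do
    lrld_blocks = list(list(chrom = "1", start = 2.8e7, end = 3.3e7,
                            n_founder_haps = 2)),
    plate_effects = list(), duplicate_pairs = 0, n_migrants = 0, seed = 58))
  ds <- sim$dataset
  auto <- which(ds$variants$chrom != "X")
  # region labels drive the informative-PC count: the region axes occupy the
  # leading PCs and the planted block surfaces just beyond them
  res <- suppressWarnings(
    iterate_lrld_pca(ds$calls, ds$variants, auto, sim$map,
                     labels = ds$samples$region, n_pcs = 8))
  expect_gte(nrow(res$regions), 1)
  tr <- sim$truth$lrld_intervals[1, ]
  inter <- sum(pmax(0, pmin(res$regions$end, tr$end) -
                      pmax(res$regions$start, tr$start)))
  union <- sum(res$regions$end - res$regions$start) + (tr$end - tr$start) - inter
  expect_gte(inter / union, 0.6)
  # cumulative regions are disjoint per chromosome
  for (ch in unique(res$regions$chrom)) {
    r <- res$regions[res$regions$chrom == ch, ]
    r <- r[order(r$start), ]
    if (nrow(r) > 1) expect_true(all(r$start[-1] > r$end[-nrow(r)]))
  }
  # no planted structure: terminates immediately with no regions
  clean <- matrix(rbinom(150 * 800, 2, 0.4), 150, 800)
  vcl <- data.frame(id = paste0("c", 1:800), chrom = "1",
                    pos = sort(sample.int(1e8, 800)))
  res2 <- iterate_lrld_pca(clean, vcl, 1:800, uniform_genetic_map("1"),
                           n_pcs = 4, n_scan_pcs = 2)
  expect_equal(res2$n_iter, 1)
  expect_equal(nrow(res2$regions), 0)
})

test_that("regional robust Mahalanobis flags migrants but spares the bulk", {
  set.seed(59)
  n <- 300
  scores <- cbind(rnorm(n), rnorm(n), rnorm(n))
  region <- rep(c("a", "b"), each = n / 2)
  scores[region == "b", 1] <- scores[region == "b", 1] + 12
  # three migrants recorded in region a but drawn around region b's centre
  scores[1:3, 1] <- rnorm(3, 12)
  out <- regional_outliers(scores, region, k = 3)
  expect_true(all(out$flag[1:3]))
  expect_lt(mean(out$flag[-(1:3)]), 0.02)
  expect_false(out$flag[which.min(rowSums(scale(scores[region == "a", ])^2))])
})

test_that("local PCA finds geographic signal only when it exists", {
  set.seed(60)
  m <- 2000
  sim <- bn_two_pops(80, m, 0.015)
  coords <- cbind(lat = ifelse(sim$pop == "A", 30, 33) + rnorm(160, 0, 0.1),
                  long = ifelse(sim$pop == "A", 110, 114) + rnorm(160, 0, 0.1))
  res <- local_pca(sim$g, coords, n_pcs = 5)
  expect_gte(res$k, 1)
  # a single assessment centre has nothing to predict
  res1 <- local_pca(sim$g, cbind(rep(30, 160), rep(110, 160)), n_pcs = 5)
  expect_equal(res1$k, 0)
  # shuffling the coordinates destroys the signal in most permutations
  nulls <- replicate(10, local_pca(sim$g, coords[sample(160), ], n_pcs = 5)$k)
  expect_gte(mean(nulls == 0), 0.8)
})

test_that("Weir-Cockerham Fst is symmetric, near zero within a population", {
  set.seed(61)
  g <- matrix(rbinom(200 * 20000, 2, rep(runif(20000, 0.05, 0.95), each = 200)),
              200, 20000)
  halves <- rep(c("x", "y"), each = 100)
  fst <- fst_matrix(g, halves)
  expect_equal(fst, t(fst))
  expect_equal(diag(fst), c(x = 0, y = 0))
  expect_lt(abs(fst["x", "y"]), 0.002)
  expect_warning(fst_matrix(g[1:30, ], rep(c("x", "y"), 15)), "fewer than 20")
})
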