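# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# direct genotype-count HWE chi-square summed over regions
oracle_hwe <- function(g, region) {
  stat <- 0; df <- 0
  for (r in unique(region)) {
    x <- g[region == r]
    x <- x[!is.na(x)]
    n <- length(x)
    if (n < 2) next
    p <- mean(x) / 2
    if (p <= 0 || p >= 1) next
    obs <- c(sum(x == 0), sum(x == 1), sum(x == 2))
    e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    stat <- stat + sum((obs - e)^2 / e)
    df <- df + 1
  }
  list(stat = stat, df = df,
       p = if (df > 0) pchisq(stat, df, lower.tail = FALSE) else NA_real_)
}

# exhaustive path enumeration for the two-state HMM posterior
oracle_hmm_posterior <- function(emis, delta_cm, rho = 1, pi_in = 0.05) {
  n <- nrow(emis)
  sw <- 1 - exp(-rho * pmax(delta_cm, 1e-6))
  trans <- lapply(seq_len(n - 1), function(k) {
    a01 <- pi_in * sw[k]; a10 <- (1 - pi_in) * sw[k]
    matrix(c(1 - a01, a01, a10, 1 - a10), 2, 2, byrow = TRUE)
  })
  init <- c(1 - pi_in, pi_in)
  paths <- as.matrix(expand.grid(rep(list(1:2), n)))
  marg <- matrix(0, n, 2)
  total <- 0
  for (k in seq_len(nrow(paths))) {
    s <- paths[k, ]
    pr <- init[s[1]] * emis[1, s[1]]
    if (n > 1) for (t in 2:n) pr <- pr * trans[[t - 1]][s[t - 1], s[t]] * emis[t, s[t]]
    total <- total + pr
    for (t in seq_len(n)) marg[t, s[t]] <- marg[t, s[t]] + pr
  }
  marg / total
}

# direct scan ROH oracle: same declared algorithm, independent implementation
oracle_roh_total <- function(g, pos, window = 50, max_het = 1, max_missing = 5,
                             min_snps = 50, min_kb = 1000, max_gap_kb = 1000) {
  n <- length(g)
  if (n < window) return(0)
  elig <- rep(FALSE, n)
  for (i in 1:(n - window + 1)) {
    w <- g[i:(i + window - 1)]
    if (sum(w == 1, na.rm = TRUE) <= max_het && sum(is.na(w)) <= max_missing)
      elig[i:(i + window - 1)] <- TRUE
  }
  total <- 0
  i <- 1
  while (i <= n) {
    if (!elig[i]) { i <- i + 1; next }
    j <- i
    while (j < n && elig[j + 1] && (pos[j + 1] - pos[j]) <= max_gap_kb * 1000)
      j <- j + 1
    kb <- (pos[j] - pos[i]) / 1000
    if ((j - i + 1) >= min_snps && kb >= min_kb) total <- total + kb
    i <- j + 1
  }
  total
}

# single-locus allele-label gene dropping: realized IBD state distribution
# for a named relationship, averaged over `reps` meiosis replicates
oracle_gene_drop <- function(type, reps = 20000) {
  counter <- c(0)
  new_person <- function() {
    counter[1] <<- counter[1] + 2
    c(counter[1] - 1, counter[1])
  }
  kid <- function(f, m) c(sample(f, 1), sample(m, 1))
  z <- c(0, 0, 0)
  for (k in seq_len(reps)) {
    counter[1] <- 0
    pair <- switch(type,
      parent_offspring = { f <- new_person(); list(f, kid(f, new_person())) },
      full_sibling = { f <- new_person(); m <- new_person()
        list(kid(f, m), kid(f, m)) },
      half_sibling = { f <- new_person()
        list(kid(f, new_person()), kid(f, new_person())) },
      second_cousin = { cp1 <- new_person(); cp2 <- new_person()
        s1 <- kid(cp1, cp2); s2 <- kid(cp1, cp2)
        p1 <- kid(s1, new_person()); p2 <- kid(s2, new_person())
        list(kid(p1, new_person()), kid(p2, new_person())) },
      triple_second_cousin = {
        cpl <- lapply(1:6, function(i) new_person())
        sibs <- lapply(c(1, 3, 5), function(i)
          list(kid(cpl[[i]], cpl[[i + 1]]), kid(cpl[[i]], cpl[[i + 1]])))
        xm <- kid(sibs[[1]][[1]], sibs[[3]][[1]])
        xf <- kid(sibs[[2]][[1]], new_person())
        ym <- kid(sibs[[1]][[2]], new_person())
        yf <- kid(sibs[[2]][[2]], sibs[[3]][[2]])
        list(kid(xf, xm), kid(yf, ym)) },
      stop("unknown type"))
    shared <- length(intersect(pair[[1]], pair[[2]]))
    z[shared + 1] <- z[shared + 1] + 1
  }
  z <- z / reps
  list(z0 = z[1], z1 = z[2], z2 = z[3], pi_hat = z[2] / 2 + z[3], reps = reps)
}

# independent greedy clumping reimplementation
oracle_clump <- function(results, ld, p1, kb, r2, p2) {
  locus <- rep(NA_character_, nrow(results))
  open <- rep(TRUE, nrow(results))
  repeat {
    cand <- which(open & results$p <= p1)
    if (!length(cand)) break
    ix <- cand[which.min(results$p[cand])]
    locus[ix] <- results$id[ix]; open[ix] <- FALSE
    for (k in which(open)) {
      if (results$chrom[k] != results$chrom[ix]) next
      if (abs(results$pos[k] - results$pos[ix]) > kb * 1000) next
      if (results$p[k] > p2) next
      rr <- suppressWarnings(cor(ld[, results$id[ix]], ld[, results$id[k]],
                                 use = "pairwise.complete.obs"))^2
      if (!is.na(rr) && rr >= r2) { locus[k] <- results$id[ix]; open[k] <- FALSE }
    }
  }
  locus
}

# Balding-Nichols two-population genotype matrices for structure tests
bn_two_pops <- function(n_per, m, f, maf_range = c(0.05, 0.95)) {
  p0 <- runif(m, maf_range[1], maf_range[2])
  draw <- function() {
    if (f > 0) {
      a <- p0 * (1 - f) / f; b <- (1 - p0) * (1 - f) / f
      rbeta(m, a, b)
    } else p0
  }
  g <- function(p, n) matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  p1 <- draw(); p2 <- draw()
  list(g = rbind(g(p1, n_per), g(p2, n_per)),
       pop = rep(c("A", "B"), each = n_per), p1 = p1, p2 = p2)
}
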