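# Pairwise relatedness: method-of-moments IBD (Z0/Z1/Z2/PI_HAT), KING-robust
# kinship, relationship classification against the study thresholds, analytic
# pedigree expectations, family-graph assembly, greedy unrelated-set selection.

# Per-locus P(IBS = k | IBD = m) sums used by the method-of-moments inversion.
# p is the counted-allele frequency vector for the loci considered.
ibs_given_ibd <- function(p) {
  q <- 1 - p
  list(e00 = 2 * p^2 * q^2,
       e10 = 4 * p^3 * q + 4 * p * q^3,
       e20 = p^4 + q^4 + 4 * p^2 * q^2,
       e11 = 2 * p^2 * q + 2 * p * q^2,
       e21 = p^3 + q^3 + p^2 * q + p * q^2)
}

mom_invert <- function(n0, n1, n2, s) {
  # s: summed P(IBS|IBD) terms over the loci actually observed for the pair
  z0 <- n0 / s$e00
  z1 <- (n1 - z0 * s$e10) / s$e11
  z2 <- (n2 - z0 * s$e20 - z1 * s$e21) / s$e22
  raw <- c(z0, z1, z2)
  z <- pmax(raw, 0)
  z <- z / sum(z)
  list(z0 = z[1], z1 = z[2], z2 = z[3], pi_hat = z[2] / 2 + z[3],
       z0_raw = raw[1], z1_raw = raw[2], z2_raw = raw[3])
}

#' Method-of-moments IBD estimate for one pair
#'
#' Inverts the expected identity-by-state distribution given allele
#' frequencies to estimate the genome proportions (Z0, Z1, Z2) shared 0/1/2
#' alleles identical by descent; PI_HAT = Z1/2 + Z2. Negative components are
#' clipped to zero and the triple renormalised; pre-clip values are retained.
#'
#' @param gi,gj genotype vectors (0/1/2/NA) over the same loci
#' @param freqs counted-allele frequencies of those loci in the analysis
#'   population
#' @param min_overlap minimum number of jointly non-missing loci
#' @return list with `z0`, `z1`, `z2`, `pi_hat`, raw (pre-clip) components,
#'   and `n_loci`
#' @export
estimate_ibd <- function(gi, gj, freqs, min_overlap = 1000) {
  ok <- !is.na(gi) & !is.na(gj) & freqs > 0 & freqs < 1
  n <- sum(ok)
  if (n < min_overlap)
    stop("only ", n, " overlapping non-missing genotypes (need ", min_overlap, ")")
  gi <- gi[ok]; gj <- gj[ok]
  d <- abs(gi - gj)
  both_het <- gi == 1L & gj == 1L
  ibs0 <- sum(d == 2L)
  ibs2 <- sum(d == 0L)
  ibs1 <- n - ibs0 - ibs2
  e <- ibs_given_ibd(freqs[ok])
  s <- list(e00 = sum(e$e00), e10 = sum(e$e10), e20 = sum(e$e20),
            e11 = sum(e$e11), e21 = sum(e$e21), e22 = n)
  out <- mom_invert(ibs0, ibs1, ibs2, s)
  out$n_loci <- n
  out
}

#' Method-of-moments IBD for many pairs of a genotype matrix
#'
#' Matrix-algebra implementation of [estimate_ibd()] over all (or selected)
#' pairs; used for duplicate discovery and within-region relatedness scans.
#'
#' @param g genotype matrix (samples x variants)
#' @param freqs counted-allele frequencies (default: estimated from `g`)
#' @param pairs optional 2-column index matrix of pairs; default all pairs
#' @return data.frame with ids/indices, `z0`, `z1`, `z2`, `pi_hat`, `n_loci`
#' @export
ibd_pairs <- function(g, freqs = NULL, pairs = NULL) {
  if (inherits(g, "genotype_dataset")) g <- g$calls
  if (is.null(freqs)) freqs <- colMeans(g, na.rm = TRUE) / 2
  keep <- freqs > 0 & freqs < 1
  g <- g[, keep, drop = FALSE]; freqs <- freqs[keep]
  n <- nrow(g)
  A0 <- (!is.na(g) & g == 0L) + 0
  A1 <- (!is.na(g) & g == 1L) + 0
  A2 <- (!is.na(g) & g == 2L) + 0
  V <- A0 + A1 + A2                      # observed indicator
  N0 <- A0 %*% t(A2); N0 <- N0 + t(N0)   # opposite homozygotes
  N2 <- A0 %*% t(A0) + A1 %*% t(A1) + A2 %*% t(A2)
  e <- ibs_given_ibd(freqs)
  wsum <- function(w) tcrossprod(sweep(V, 2, w, `*`), V)
  S00 <- wsum(e$e00); S10 <- wsum(e$e10); S20 <- wsum(e$e20)
  S11 <- wsum(e$e11); S21 <- wsum(e$e21); NN <- tcrossprod(V)
  if (is.null(pairs)) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  } else idx <- pairs
  res <- lapply(seq_len(nrow(idx)), function(k) {
    i <- idx[k, 1]; j <- idx[k, 2]
    nv <- NN[i, j]
    s <- list(e00 = S00[i, j], e10 = S10[i, j], e20 = S20[i, j],
              e11 = S11[i, j], e21 = S21[i, j], e22 = nv)
    z <- mom_invert(N0[i, j], nv - N0[i, j] - N2[i, j], N2[i, j], s)
    data.frame(i = i, j = j, z0 = z$z0, z1 = z$z1, z2 = z$z2,
               pi_hat = z$pi_hat, n_loci = nv)
  })
  out <- do.call(rbind, res)
  if (!is.null(rownames(g))) {
    out$id1 <- rownames(g)[out$i]
    out$id2 <- rownames(g)[out$j]
  }
  out
}

#' KING-robust kinship coefficient for one pair
#'
#' Between-family robust estimator from heterozygote concordance and
#' opposite-homozygote counts:
#' kinship = (N_het,het - 2 N_AA,aa) / (N_het(i) + N_het(j)).
#'
#' @param gi,gj genotype vectors (0/1/2/NA)
#' @return kinship coefficient (NA with a warning if a sample has no
#'   heterozygous calls on the overlap)
#' @export
king_kinship <- function(gi, gj) {
  ok <- !is.na(gi) & !is.na(gj)
  gi <- gi[ok]; gj <- gj[ok]
  nhet_i <- sum(gi == 1L); nhet_j <- sum(gj == 1L)
  if (nhet_i == 0 || nhet_j == 0) {
    warning("kinship undefined: a sample is fully homozygous on the overlap")
    return(NA_real_)
  }
  nhh <- sum(gi == 1L & gj == 1L)
  nopp <- sum(abs(gi - gj) == 2L)
  (nhh - 2 * nopp) / (nhet_i + nhet_j)
}

#' KING-robust kinship for all pairs of a genotype matrix
#' @param g genotype matrix (samples x variants) or a `genotype_dataset`
#' @return symmetric kinship matrix
#' @export
king_matrix <- function(g) {
  if (inherits(g, "genotype_dataset")) g <- g$calls
  H <- (!is.na(g) & g == 1L) + 0
  A0 <- (!is.na(g) & g == 0L) + 0
  A2 <- (!is.na(g) & g == 2L) + 0
  V <- (!is.na(g)) + 0
  Nhh <- tcrossprod(H)
  Nopp <- A0 %*% t(A2); Nopp <- Nopp + t(Nopp)
  Nhet_i <- H %*% t(V)                # het in i among jointly observed
  denom <- Nhet_i + t(Nhet_i)
  k <- (Nhh - 2 * Nopp) / denom
  diag(k) <- 0.5
  k
}

#' Classify a pairwise relationship from its IBD estimate
#'
#' Thresholds: PI_HAT > 0.95 duplicate/MZ; PI_HAT > 0.375 first degree,
#' split into parent-child (Z0 < 0.05 and Z1 > 0.5, parent the older of the
#' pair) versus full sibling; PI_HAT > 0.1875 second degree; kinship in
#' (0.0442, 0.0884] third degree; otherwise unrelated.
#'
#' @param ibd list or one-row data.frame with `z0`, `z1`, `pi_hat`
#' @param ages optional numeric length-2 ages of (i, j), used for
#'   parent-child direction
#' @param kinship optional KING kinship, used only for the third-degree band
#' @return list with `call`, `parent` (1, 2 or NA), and `note`
#' @export
classify_relationship <- function(ibd, ages = NULL, kinship = NULL) {
  ph <- ibd$pi_hat
  note <- NA_character_; parent <- NA_integer_
  if (ph > 0.95) call <- "duplicate_or_MZ"
  else if (ph > 0.375) {
    if (ibd$z0 < 0.05 && ibd$z1 > 0.5) {
      call <- "parent_child"
      if (!is.null(ages) && !any(is.na(ages))) {
        if (ages[1] == ages[2]) note <- "direction unresolved: equal ages"
        else parent <- which.max(ages)
      } else note <- "direction unresolved: ages unavailable"
    } else call <- "full_sibling"
  } else if (ph > 0.1875) call <- "second_degree"
  else if (!is.null(kinship) && !is.na(kinship) &&
           kinship > 0.0442 && kinship <= 0.0884) call <- "third_degree"
  else call <- "unrelated"
  list(call = call, parent = parent, note = note)
}

#' Analytic expected IBD for a pedigree relationship
#'
#' For a union of independent pedigree connections, PI_HAT equals twice the
#' summed path kinships; each connection contributes
#' `ancestors * (1/2)^(meioses + 1)` kinship. Z2 accounts for connections on
#' complementary parental channels (e.g. double first cousins, or the triple
#' second cousins characteristic of consanguineous populations, expected
#' PI_HAT 0.09375).
#'
#' @param relationship a named relationship (`"duplicate"`,
#'   `"parent_offspring"`, `"full_sibling"`, `"half_sibling"`,
#'   `"second_cousin"`, `"triple_second_cousin"`, `"unrelated"`), or `NULL`
#'   when `connections` is given
#' @param connections data.frame with columns `meioses`, `ancestors` and
#'   optionally `channel_i`/`channel_j` (`"m"`/`"f"`: which parent of each
#'   pair member carries the connection; defaults cycle mm, ff, mf, fm)
#' @return list with `z0`, `z1`, `z2`, `pi_hat`
#' @export
expected_ibd <- function(relationship = NULL, connections = NULL) {
  named <- list(
    duplicate = c(0, 0, 1),
    parent_offspring = c(0, 1, 0),
    full_sibling = c(0.25, 0.5, 0.25),
    half_sibling = c(0.5, 0.5, 0),
    unrelated = c(1, 0, 0))
  if (!is.null(relationship) && relationship %in% names(named)) {
    z <- named[[relationship]]
    return(list(z0 = z[1], z1 = z[2], z2 = z[3], pi_hat = z[2] / 2 + z[3]))
  }
  if (!is.null(relationship)) {
    connections <- switch(relationship,
      second_cousin = data.frame(meioses = 6, ancestors = 2),
      triple_second_cousin = data.frame(meioses = c(6, 6, 6),
                                        ancestors = c(2, 2, 2),
                                        channel_i = c("m", "f", "m"),
                                        channel_j = c("m", "f", "f")),
      stop("unknown relationship: ", relationship))
  }
  if (is.null(connections) || !all(c("meioses", "ancestors") %in% names(connections)))
    stop("connections must have columns 'meioses' and 'ancestors'")
  if (any(connections$meioses < 1 | connections$ancestors < 1))
    stop("malformed descriptor: meioses and ancestors must be positive")
  nc <- nrow(connections)
  if (is.null(connections$channel_i)) {
    cyc <- matrix(c("m", "m", "f", "f", "m", "f", "f", "m"), ncol = 2,
                  byrow = TRUE)
    k <- ((seq_len(nc) - 1) %% 4) + 1
    connections$channel_i <- cyc[k, 1]
    connections$channel_j <- cyc[k, 2]
  }
  # per-connection probability that the focal parental allele of i is IBD to
  # the connected parental allele of j: 4 * kinship
  phi <- connections$ancestors * 0.5^(connections$meioses + 1)
  share <- 4 * phi
  ch <- paste0(connections$channel_i, connections$channel_j)
  s <- vapply(c("mm", "mf", "fm", "ff"),
              function(x) sum(share[ch == x]), 0)
  if (any(s > 1)) stop("malformed descriptor: channel sharing probability > 1")
  z2 <- s["mm"] * s["ff"] + s["mf"] * s["fm"]
  z1 <- sum(s) - 2 * z2
  z0 <- 1 - z1 - z2
  list(z0 = unname(z0), z1 = unname(z1), z2 = unname(z2),
       pi_hat = unname(z1 / 2 + z2))
}

#' Assemble family structures from pairwise relationship calls
#'
#' Connected components over first-degree edges; sibling groups as cliques
#' of full-sibling edges (non-clique groups flagged for review as potential
#' three-quarter siblings); trios where a sample has parent-child edges to
#' two samples that are not themselves first-degree relatives.
#'
#' @param calls data.frame with `id1`, `id2`, `call`, and optionally `parent`
#'   (1 or 2: which member is the parent)
#' @return list with `components`, `sib_groups`, `trios`, `parent_arcs`,
#'   `review`
#' @export
build_families <- function(calls) {
  first <- calls[calls$call %in% c("parent_child", "full_sibling"), , drop = FALSE]
  nodes <- unique(c(first$id1, first$id2))
  if (!length(nodes))
    return(list(components = list(), sib_groups = list(), trios = list(),
                parent_arcs = data.frame(parent = character(0),
                                         child = character(0)),
                review = character(0)))
  g <- igraph::graph_from_data_frame(first[, c("id1", "id2")], directed = FALSE,
                                     vertices = nodes)
  comp <- igraph::components(g)
  components <- split(nodes, comp$membership[nodes])

  sib <- first[first$call == "full_sibling", , drop = FALSE]
  review <- character(0)
  sib_groups <- list()
  if (nrow(sib)) {
    gs <- igraph::graph_from_data_frame(sib[, c("id1", "id2")], directed = FALSE)
    cs <- igraph::components(gs)
    mem <- split(names(cs$membership), cs$membership)
    for (grp in mem) {
      k <- length(grp)
      n_edges <- sum((sib$id1 %in% grp) & (sib$id2 %in% grp))
      if (n_edges == k * (k - 1) / 2) sib_groups[[length(sib_groups) + 1]] <- grp
      else review <- c(review, grp)  # intermediate patterns, e.g. 3/4 sibs
    }
  }

  pc <- first[first$call == "parent_child", , drop = FALSE]
  parent_arcs <- data.frame(parent = character(0), child = character(0))
  if (nrow(pc)) {
    hasdir <- !is.na(pc$parent)
    parent_arcs <- data.frame(
      parent = ifelse(pc$parent[hasdir] == 1, pc$id1[hasdir], pc$id2[hasdir]),
      child = ifelse(pc$parent[hasdir] == 1, pc$id2[hasdir], pc$id1[hasdir]),
      stringsAsFactors = FALSE)
    if (nrow(parent_arcs)) {
      gd <- igraph::graph_from_data_frame(parent_arcs, directed = TRUE)
      if (!igraph::is_dag(gd)) {
        cyc <- names(igraph::V(gd))[igraph::feedback_arc_set(gd)]
        stop("parent-child arcs contain a cycle involving: ",
             paste(unique(c(parent_arcs$parent, parent_arcs$child)), collapse = ", "))
      }
    }
  }
  trios <- list()
  if (nrow(parent_arcs)) {
    for (chld in unique(parent_arcs$child)) {
      par <- parent_arcs$parent[parent_arcs$child == chld]
      if (length(par) == 2) {
        couple_first <- any((first$id1 == par[1] & first$id2 == par[2]) |
                              (first$id1 == par[2] & first$id2 == par[1]))
        if (!couple_first)
          trios[[length(trios) + 1]] <- list(child = chld, parents = par)
      }
    }
  }
  list(components = components, sib_groups = sib_groups, trios = trios,
       parent_arcs = parent_arcs, review = unique(review))
}

#' Greedy selection of a maximal unrelated sample set
#'
#' Iteratively removes the sample involved in the most pairs above the
#' kinship cutoff (ties broken by lower call rate, then lexicographic id)
#' until no pair exceeds the cutoff.
#'
#' @param kinship symmetric kinship matrix with sample ids as dimnames, or a
#'   pair data.frame with `id1`, `id2`, `kinship`
#' @param cutoff kinship cutoff (default 0.05)
#' @param call_rates optional named call-rate vector used for tie-breaking
#' @return character vector of retained sample ids
#' @export
greedy_unrelated_set <- function(kinship, cutoff = 0.05, call_rates = NULL) {
  if (is.matrix(kinship)) {
    ids <- rownames(kinship)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(kinship)))
    ut <- which(upper.tri(kinship) & kinship > cutoff, arr.ind = TRUE)
    pairs <- data.frame(id1 = ids[ut[, 1]], id2 = ids[ut[, 2]],
                        stringsAsFactors = FALSE)
  } else {
    pairs <- kinship[kinship$kinship > cutoff, c("id1", "id2"), drop = FALSE]
    ids <- unique(c(kinship$id1, kinship$id2))
  }
  all_pairs <- pairs
  keep <- ids
  removed <- character(0)
  while (nrow(pairs) > 0) {
    deg <- table(c(pairs$id1, pairs$id2))
    worst <- names(deg)[deg == max(deg)]
    if (length(worst) > 1 && !is.null(call_rates)) {
      cr <- call_rates[worst]
      worst <- worst[order(cr, worst)]
    } else worst <- sort(worst)
    drop <- worst[1]
    keep <- setdiff(keep, drop)
    removed <- c(removed, drop)
    pairs <- pairs[pairs$id1 != drop & pairs$id2 != drop, , drop = FALSE]
  }
  # maximality repair: re-admit removed samples whose every above-cutoff
  # partner was itself removed later
  for (s in sort(removed)) {
    partners <- c(all_pairs$id2[all_pairs$id1 == s],
                  all_pairs$id1[all_pairs$id2 == s])
    if (!any(partners %in% keep)) keep <- union(keep, s)
  }
  keep
}
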