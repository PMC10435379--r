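# Synthetic cohort simulator: structured founder populations (Balding-Nichols),
# gamete-dropping pedigrees, planted plate/batch artifacts, long-range-LD
# haplotype blocks, sex-chromosome karyotypes, plate/box layout with
# intentional duplicates and case-ascertained genotyping selection.

#' Build a uniform genetic map
#'
#' Linear map with a constant recombination rate, the default scale used by
#' the simulator (1 cM/Mbp).
#'
#' @param chroms chromosome labels
#' @param length_bp physical length per chromosome (recycled)
#' @param cm_per_mb recombination rate in cM per Mbp (recycled)
#' @param points anchor points per chromosome
#' @return data.frame with columns `chrom`, `pos`, `cm`; positions strictly
#'   increasing and cM non-decreasing within chromosome
#' @export
uniform_genetic_map <- function(chroms, length_bp = 1e8, cm_per_mb = 1,
                                points = 25) {
  length_bp <- rep_len(length_bp, length(chroms))
  cm_per_mb <- rep_len(cm_per_mb, length(chroms))
  out <- lapply(seq_along(chroms), function(i) {
    pos <- unique(round(seq(1, length_bp[i], length.out = points)))
    data.frame(chrom = chroms[i], pos = pos, cm = pos / 1e6 * cm_per_mb[i])
  })
  do.call(rbind, out)
}

# linear interpolation of genetic position, clamped at map ends
interp_cm <- function(map, chrom, pos) {
  out <- numeric(length(pos))
  for (ch in unique(chrom)) {
    i <- chrom == ch
    sub <- map[map$chrom == ch, ]
    if (nrow(sub) == 0) stop("chromosome ", ch, " not covered by the genetic map")
    out[i] <- stats::approx(sub$pos, sub$cm, xout = pos[i], rule = 2)$y
  }
  out
}

# randomly phase an unphased genotype vector into two haplotypes
rand_phase <- function(g) {
  h1 <- as.integer(g >= 1)
  h2 <- as.integer(g == 2)
  het <- which(!is.na(g) & g == 1L)
  sw <- het[stats::runif(length(het)) < 0.5]
  h1[sw] <- 0L; h2[sw] <- 1L
  h1[is.na(g)] <- NA_integer_; h2[is.na(g)] <- NA_integer_
  rbind(h1, h2)
}

# one recombined gamete from a 2 x V haplotype matrix.
# map = NULL means unlinked loci (independent assortment per variant).
make_gamete <- function(haps, variants = NULL, map = NULL) {
  v <- ncol(haps)
  if (is.null(map)) {
    pick <- sample(c(1L, 2L), v, replace = TRUE)
    return(ifelse(pick == 1L, haps[1, ], haps[2, ]))
  }
  cm <- interp_cm(map, variants$chrom, variants$pos)
  out <- integer(v)
  for (ch in unique(variants$chrom)) {
    i <- which(variants$chrom == ch)
    cmi <- cm[i]
    len <- max(cmi) - min(cmi)
    nxo <- stats::rpois(1, len / 100)
    xo <- sort(stats::runif(nxo, min(cmi), max(cmi)))
    src <- (sample(0:1, 1) + findInterval(cmi, xo)) %% 2 + 1
    out[i] <- ifelse(src == 1L, haps[1, i], haps[2, i])
  }
  out
}

#' Drop gametes through one meiosis per parent
#'
#' Produces offspring genotypes as one recombined gamete from each parent.
#' Crossover counts per chromosome are Poisson with mean equal to the map
#' length in Morgans; `map = NULL` treats all loci as unlinked.
#'
#' @param father,mother either a 2 x V phased haplotype matrix or an
#'   unphased genotype vector (phase is then randomised)
#' @param variants variant map (`chrom`, `pos`); required when `map` is given
#' @param map genetic map as from [uniform_genetic_map()], or `NULL`
#' @param haplotypes if `TRUE`, return the two gametes as a 2 x V matrix
#'   instead of their sum
#' @return offspring genotype vector (0/1/2), or a haplotype matrix
#' @export
drop_gametes <- function(father, mother, variants = NULL, map = NULL,
                         haplotypes = FALSE) {
  if (!is.matrix(father)) father <- rand_phase(father)
  if (!is.matrix(mother)) mother <- rand_phase(mother)
  if (!is.null(map)) {
    if (is.null(variants)) stop("variant map required when a genetic map is supplied")
    missing_chr <- setdiff(unique(variants$chrom), unique(map$chrom))
    if (length(missing_chr))
      stop("unmapped variants on chromosome(s): ", paste(missing_chr, collapse = ", "))
  }
  g1 <- make_gamete(father, variants, map)
  g2 <- make_gamete(mother, variants, map)
  if (haplotypes) rbind(g1, g2) else as.integer(g1 + g2)
}

# apply independent genotyping errors: with prob `rate` move the call to an
# adjacent genotype class (hom <-> het), the way array miscalls arise from
# neighbouring clusters; hom -> opposite hom essentially never happens
add_genotype_errors <- function(g, rate) {
  if (rate <= 0) return(g)
  hit <- which(!is.na(g) & stats::runif(length(g)) < rate)
  for (i in hit) g[i] <- if (g[i] == 1L) sample(c(0L, 2L), 1) else 1L
  g
}

#' Simulate pairs of relatives by gamete-dropping
#'
#' Unlinked loci with allele frequencies drawn uniformly; founders are
#' Hardy-Weinberg draws, descendants are produced by Mendelian transmission.
#' Supported relationships include the consanguineous triple-second-cousin
#' configuration (three independent second-cousin connections, expected
#' PI_HAT 0.09375).
#'
#' @param type one of `"duplicate"`, `"parent_offspring"`, `"full_sibling"`,
#'   `"half_sibling"`, `"second_cousin"`, `"triple_second_cousin"`,
#'   `"unrelated"`
#' @param n_pairs number of independent pairs
#' @param n_snps unlinked autosomal SNPs per pair set
#' @param maf_range range of the uniform allele-frequency draw
#' @param error_rate per-genotype error probability applied independently to
#'   each member of the pair
#' @return list with `geno_i`, `geno_j` (n_pairs x n_snps matrices), `freqs`,
#'   and `type`
#' @export
simulate_relative_pairs <- function(type, n_pairs, n_snps = 10000,
                                    maf_range = c(0.05, 0.5),
                                    error_rate = 0) {
  type <- match.arg(type, c("duplicate", "parent_offspring", "full_sibling",
                            "half_sibling", "second_cousin",
                            "triple_second_cousin", "unrelated"))
  p <- stats::runif(n_snps, maf_range[1], maf_range[2])
  founder <- function() rbind(stats::rbinom(n_snps, 1, p), stats::rbinom(n_snps, 1, p))
  child <- function(f, m) rbind(make_gamete(f), make_gamete(m))
  gi <- matrix(0L, n_pairs, n_snps); gj <- matrix(0L, n_pairs, n_snps)
  for (k in seq_len(n_pairs)) {
    pair <- switch(type,
      duplicate = { a <- founder(); list(a, a) },
      unrelated = list(founder(), founder()),
      parent_offspring = { f <- founder(); m <- founder(); list(f, child(f, m)) },
      full_sibling = { f <- founder(); m <- founder(); list(child(f, m), child(f, m)) },
      half_sibling = { f <- founder(); list(child(f, founder()), child(f, founder())) },
      second_cousin = {
        cpl <- list(founder(), founder())           # shared great-grandparents
        s1 <- child(cpl[[1]], cpl[[2]]); s2 <- child(cpl[[1]], cpl[[2]])
        p1 <- child(s1, founder()); p2 <- child(s2, founder())
        list(child(p1, founder()), child(p2, founder()))
      },
      triple_second_cousin = {
        # three ancestral couples, each linking the pair through a distinct
        # second-cousin connection (channels mother-mother, father-father,
        # mother-father); expected PI_HAT = 3 x 0.03125 = 0.09375
        cpl <- lapply(1:3, function(i) list(founder(), founder()))
        sib <- lapply(cpl, function(cp) list(child(cp[[1]], cp[[2]]),
                                             child(cp[[1]], cp[[2]])))
        xm <- child(sib[[1]][[1]], sib[[3]][[1]])
        xf <- child(sib[[2]][[1]], founder())
        ym <- child(sib[[1]][[2]], founder())
        yf <- child(sib[[2]][[2]], sib[[3]][[2]])
        list(child(xf, xm), child(yf, ym))
      })
    gi[k, ] <- add_genotype_errors(colSums(pair[[1]]), error_rate)
    gj[k, ] <- add_genotype_errors(colSums(pair[[2]]), error_rate)
  }
  list(geno_i = gi, geno_j = gj, freqs = p, type = type)
}

# ---- cohort simulation ------------------------------------------------------

#' Simulation configuration
#'
#' Defaults describe a desk-scale cohort: 10 discrete recruitment regions on
#' a north-south gradient of differentiation (Balding-Nichols), two autosomes
#' plus chromosome X, within-region families, one planted long-range-LD
#' block, one plate with genotype-calling artifacts, sex-chromosome
#' aneuploidies, 96-well plates with intentional duplicates, and box-level
#' genotyping selection with disease-case over-ascertainment.
#'
#' @param n_regions number of recruitment regions
#' @param samples_per_region cohort members recruited per region
#' @param n_variants autosomal variants per autosome
#' @param n_autosomes autosomes simulated
#' @param n_x_variants chromosome X variants
#' @param fst per-region Balding-Nichols differentiation in \[0, 1); default
#'   is a latitude-linked gradient
#' @param region_coords data.frame `lat`/`long` per region
#' @param pedigree_spec list of counts: `trios`, `sib_pairs`,
#'   `half_sib_pairs`, `parent_offspring_pairs`, `consanguineous_pairs`
#'   (triple second cousins), `first_cousin_offspring` (inbred individuals)
#' @param lrld_blocks list of blocks `list(chrom, start, end, n_founder_haps)`
#' @param plate_effects list of `list(plate, n_probesets, delta)`; `delta` is
#'   the probability that a heterozygous call on the affected plate is
#'   miscalled as the counted-allele homozygote
#' @param aneuploidy_counts named counts of planted karyotypes among
#'   `XO`, `XO_mosaic`, `XXX`, `XXY`
#' @param duplicate_pairs intentional duplicate samples placed at fixed
#'   plate positions (well H12 holds a duplicate of D1 on the previous plate)
#' @param n_migrants samples recorded in one region but genotypically from the
#'   most distant region
#' @param n_low_dqc,n_low_callrate planted initial-QC failures
#' @param box_size storage-box capacity
#' @param box_fraction_high,box_fraction_low,p_low_box ranges of per-box
#'   genotyping-selection fractions and the probability a box is a
#'   low-selection box
#' @param case_ascertainment named list per disease:
#'   `list(prevalence =, p_select =)`; `p_select` is the probability a case is
#'   selected for genotyping regardless of its box
#' @param missing_rate random genotype missingness
#' @param dup_error_rate genotype discordance between duplicate copies
#' @param plates_per_batch plates co-clustered per genotyping batch
#' @param seed integer seed; fixed seed gives identical output
#' @return a `sim_config` list
#' @export
sim_config <- function(n_regions = 10, samples_per_region = 100,
                       n_variants = 1500, n_autosomes = 2, n_x_variants = 300,
                       fst = NULL, region_coords = NULL,
                       pedigree_spec = list(trios = 2, sib_pairs = 3,
                                            half_sib_pairs = 2,
                                            parent_offspring_pairs = 2,
                                            consanguineous_pairs = 2,
                                            first_cousin_offspring = 2),
                       lrld_blocks = list(list(chrom = "1", start = 3.0e7,
                                               end = 3.2e7, n_founder_haps = 4)),
                       plate_effects = list(list(plate = 2, n_probesets = 12,
                                                 delta = 0.5)),
                       aneuploidy_counts = c(XO = 2, XO_mosaic = 2, XXX = 3,
                                             XXY = 2),
                       duplicate_pairs = 3, n_migrants = 3,
                       n_low_dqc = 2, n_low_callrate = 2,
                       box_size = 96,
                       box_fraction_high = c(0.7, 1),
                       box_fraction_low = c(0.05, 0.35), p_low_box = 0.25,
                       case_ascertainment = list(
                         disease_a = list(prevalence = 0.02, p_select = 0.9)),
                       missing_rate = 0.002, dup_error_rate = 0.002,
                       plates_per_batch = 3, seed = 1) {
  if (is.null(fst)) fst <- seq(0.005, 0.035, length.out = n_regions)
  fst <- rep_len(fst, n_regions)
  if (any(fst < 0 | fst >= 1)) stop("fst must lie in [0, 1)")
  if (is.null(region_coords))
    region_coords <- data.frame(lat = seq(23, 46, length.out = n_regions),
                                long = seq(102, 127, length.out = n_regions))
  if (nrow(region_coords) != n_regions)
    stop("region_coords must have one row per region")
  counts <- c(n_regions = n_regions, samples_per_region = samples_per_region,
              n_variants = n_variants, n_autosomes = n_autosomes,
              n_x_variants = n_x_variants, duplicate_pairs = duplicate_pairs,
              unlist(pedigree_spec))
  if (any(counts < 0)) stop("counts must be non-negative: ",
                            paste(names(counts)[counts < 0], collapse = ", "))
  fr <- c(box_fraction_high, box_fraction_low, p_low_box, missing_rate,
          dup_error_rate)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  ped_total <- 3 * pedigree_spec$trios + 2 * pedigree_spec$sib_pairs +
    2 * pedigree_spec$half_sib_pairs + pedigree_spec$parent_offspring_pairs
  if (ped_total > samples_per_region)
    stop("pedigree_spec requires more samples than samples_per_region")
  structure(list(n_regions = n_regions, samples_per_region = samples_per_region,
                 n_variants = n_variants, n_autosomes = n_autosomes,
                 n_x_variants = n_x_variants, fst = fst,
                 region_coords = region_coords, pedigree_spec = pedigree_spec,
                 lrld_blocks = lrld_blocks, plate_effects = plate_effects,
                 aneuploidy_counts = aneuploidy_counts,
                 duplicate_pairs = duplicate_pairs, n_migrants = n_migrants,
                 n_low_dqc = n_low_dqc, n_low_callrate = n_low_callrate,
                 box_size = box_size, box_fraction_high = box_fraction_high,
                 box_fraction_low = box_fraction_low, p_low_box = p_low_box,
                 case_ascertainment = case_ascertainment,
                 missing_rate = missing_rate, dup_error_rate = dup_error_rate,
                 plates_per_batch = plates_per_batch, seed = as.integer(seed)),
            class = "sim_config")
}

# Balding-Nichols frequencies: Beta(p(1-F)/F, (1-p)(1-F)/F) around ancestral p
bn_freqs <- function(p_anc, f) {
  if (f <= 0) return(p_anc)
  a <- p_anc * (1 - f) / f
  b <- (1 - p_anc) * (1 - f) / f
  stats::rbeta(length(p_anc), a, b)
}

#' Simulate a full synthetic cohort
#'
#' Generates genotypes, intensity and clustering metrics, plate/box layout
#' and a complete ground-truth label set for a structured cohort. See
#' [sim_config()] for the generative assumptions.
#'
#' @param config a [sim_config()]
#' @return list of class `qcpop_sim` with elements `dataset`
#'   (a [genotype_dataset()] of genotyped samples, duplicates included),
#'   `sample_metrics`, `cluster_metrics`, `truth`, `map`, `cohort` (full
#'   manifest including ungenotyped members) and `config`
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cf <- config

  # ---- variant map ----
  auto <- as.character(seq_len(cf$n_autosomes))
  vlist <- lapply(auto, function(ch) {
    pos <- sort(sample.int(1e8, cf$n_variants))
    data.frame(id = sprintf("chr%s_%07d", ch, seq_along(pos)), chrom = ch,
               pos = pos, stringsAsFactors = FALSE)
  })
  posx <- sort(sample.int(1e8, cf$n_x_variants))
  vlist <- c(vlist, list(data.frame(id = sprintf("chrX_%07d", seq_along(posx)),
                                    chrom = "X", pos = posx,
                                    stringsAsFactors = FALSE)))
  variants <- do.call(rbind, vlist)
  alle <- matrix(sample(c("A", "C", "G", "T"), 2 * nrow(variants), replace = TRUE),
                 ncol = 2)
  same <- alle[, 1] == alle[, 2]
  alle[same, 2] <- vapply(alle[same, 1],
                          function(a) sample(setdiff(c("A", "C", "G", "T"), a), 1), "")
  variants$a1 <- alle[, 1]; variants$a2 <- alle[, 2]
  variants$probeset <- paste0("AX-", seq_len(nrow(variants)))
  map <- uniform_genetic_map(c(auto, "X"))
  nv <- nrow(variants)
  is_x <- variants$chrom == "X"

  # ---- allele frequencies ----
  p_anc <- stats::runif(nv, 0.05, 0.95)
  p_reg <- sapply(seq_len(cf$n_regions), function(r) bn_freqs(p_anc, cf$fst[r]))

  # ---- cohort manifest (pre-genotyping) ----
  n_base <- cf$n_regions * cf$samples_per_region
  cohort <- data.frame(
    sample_id = sprintf("S%05d", seq_len(n_base)),
    region = rep(sprintf("region_%02d", seq_len(cf$n_regions)),
                 each = cf$samples_per_region),
    region_idx = rep(seq_len(cf$n_regions), each = cf$samples_per_region),
    stringsAsFactors = FALSE)
  cohort$lat <- cf$region_coords$lat[cohort$region_idx]
  cohort$long <- cf$region_coords$long[cohort$region_idx]
  cohort$sex <- sample(c("M", "F"), n_base, replace = TRUE)
  cohort$age <- sample(40:79, n_base, replace = TRUE)

  # diseases and storage boxes
  cohort$disease <- NA_character_
  for (d in names(cf$case_ascertainment)) {
    hit <- is.na(cohort$disease) &
      stats::runif(n_base) < cf$case_ascertainment[[d]]$prevalence
    cohort$disease[hit] <- d
  }
  ord <- sample.int(n_base)
  cohort$box <- integer(n_base)
  cohort$box[ord] <- (seq_len(n_base) - 1) %/% cf$box_size + 1
  n_box <- max(cohort$box)
  low_box <- stats::runif(n_box) < cf$p_low_box
  box_frac <- ifelse(low_box,
                     stats::runif(n_box, cf$box_fraction_low[1], cf$box_fraction_low[2]),
                     stats::runif(n_box, cf$box_fraction_high[1], cf$box_fraction_high[2]))

  # genotyping selection: per-box random fraction plus case over-ascertainment
  sel <- stats::runif(n_base) < box_frac[cohort$box]
  for (d in names(cf$case_ascertainment)) {
    case <- !is.na(cohort$disease) & cohort$disease == d
    sel[case] <- sel[case] |
      (stats::runif(sum(case)) < cf$case_ascertainment[[d]]$p_select)
  }
  cohort$genotyped <- sel
  cohort$ascertainment <- ifelse(sel & !is.na(cohort$disease), cohort$disease,
                                 ifelse(sel, "random", NA))

  # ---- founder haplotypes for genotyped base members ----
  gidx <- which(cohort$genotyped)
  ng <- length(gidx)
  H1 <- matrix(0L, ng, nv); H2 <- matrix(0L, ng, nv)
  reg_of <- cohort$region_idx[gidx]

  # migrants: recorded region stays, genotypes drawn from most distant region
  migrants <- integer(0)
  if (cf$n_migrants > 0 && cf$n_regions > 1) {
    migrants <- sample(seq_len(ng), min(cf$n_migrants, ng))
  }
  src_reg <- reg_of
  if (length(migrants)) {
    src_reg[migrants] <- vapply(reg_of[migrants], function(r)
      which.max(abs(cf$region_coords$lat - cf$region_coords$lat[r])), 1L)
  }
  for (r in unique(src_reg)) {
    i <- which(src_reg == r)
    H1[i, ] <- matrix(stats::rbinom(length(i) * nv, 1, rep(p_reg[, r], each = length(i))),
                      length(i), nv)
    H2[i, ] <- matrix(stats::rbinom(length(i) * nv, 1, rep(p_reg[, r], each = length(i))),
                      length(i), nv)
  }

  # ---- planted long-range LD: founder haplotypes in the block copy one of a
  # small pool of template haplotypes ----
  lrld_truth <- data.frame(chrom = character(0), start = numeric(0),
                           end = numeric(0))
  for (blk in cf$lrld_blocks) {
    j <- which(variants$chrom == blk$chrom & variants$pos >= blk$start &
                 variants$pos <= blk$end)
    if (!length(j)) next
    k <- if (is.null(blk$n_founder_haps)) 4 else blk$n_founder_haps
    tmpl <- matrix(stats::rbinom(k * length(j), 1, rep(p_anc[j], each = k)),
                   k, length(j))
    H1[, j] <- tmpl[sample.int(k, ng, replace = TRUE), , drop = FALSE]
    H2[, j] <- tmpl[sample.int(k, ng, replace = TRUE), , drop = FALSE]
    lrld_truth <- rbind(lrld_truth,
                        data.frame(chrom = blk$chrom, start = blk$start,
                                   end = blk$end))
  }

  # male founders: haploid X (second haplotype mirrors the first)
  sexg <- cohort$sex[gidx]
  H2[sexg == "M", is_x] <- H1[sexg == "M", is_x]

  # ---- pedigrees: children appended as extra genotyped cohort members ----
  ped <- cf$pedigree_spec
  relationships <- list(); inbred_ids <- character(0)
  extra_H1 <- list(); extra_H2 <- list(); extra_rows <- list()
  used <- rep(FALSE, ng)
  next_id <- n_base
  pick_founder <- function(region, sex = NULL) {
    cand <- which(reg_of == region & !used &
                    (if (is.null(sex)) TRUE else sexg == sex))
    if (!length(cand)) stop("pedigree_spec larger than available founders in region ",
                            region)
    i <- cand[1]; used[i] <<- TRUE
    i
  }
  new_child <- function(fa_h, mo_h, region, sex = NULL) {
    if (is.null(sex)) sex <- sample(c("M", "F"), 1)
    g <- drop_gametes(fa_h, mo_h, variants, map, haplotypes = TRUE)
    if (sex == "M") g[1, is_x] <- g[2, is_x]  # son: haploid maternal X
    # daughters: paternal X is the father's (possibly mirrored) X haplotype
    next_id <<- next_id + 1
    row <- data.frame(sample_id = sprintf("S%05d", next_id),
                      region = sprintf("region_%02d", region),
                      region_idx = region,
                      lat = cf$region_coords$lat[region],
                      long = cf$region_coords$long[region],
                      sex = sex, age = sample(18:35, 1), disease = NA,
                      box = NA_integer_, genotyped = TRUE,
                      ascertainment = "random", stringsAsFactors = FALSE)
    extra_rows[[length(extra_rows) + 1]] <<- row
    extra_H1[[length(extra_H1) + 1]] <<- g[1, ]
    extra_H2[[length(extra_H2) + 1]] <<- g[2, ]
    list(id = row$sample_id, haps = g)
  }
  hap_of <- function(i) rbind(H1[i, ], H2[i, ])
  rel <- function(a, b, type) relationships[[length(relationships) + 1]] <<-
    data.frame(id1 = a, id2 = b, type = type, stringsAsFactors = FALSE)
  regions_cycle <- rep_len(seq_len(cf$n_regions),
                           max(1, ped$trios + ped$sib_pairs + ped$half_sib_pairs +
                                 ped$parent_offspring_pairs +
                                 ped$consanguineous_pairs +
                                 ped$first_cousin_offspring))
  rc <- 0
  nxt_region <- function() { rc <<- rc + 1; regions_cycle[rc] }
  for (k in seq_len(ped$trios)) {
    r <- nxt_region()
    fa <- pick_founder(r, "M"); mo <- pick_founder(r, "F")
    ch <- new_child(hap_of(fa), hap_of(mo), r)
    rel(cohort$sample_id[gidx[fa]], ch$id, "parent_offspring")
    rel(cohort$sample_id[gidx[mo]], ch$id, "parent_offspring")
  }
  for (k in seq_len(ped$sib_pairs)) {
    r <- nxt_region()
    fa <- pick_founder(r, "M"); mo <- pick_founder(r, "F")
    c1 <- new_child(hap_of(fa), hap_of(mo), r)
    c2 <- new_child(hap_of(fa), hap_of(mo), r)
    rel(c1$id, c2$id, "full_sibling")
  }
  for (k in seq_len(ped$half_sib_pairs)) {
    r <- nxt_region()
    fa <- pick_founder(r, "M")
    c1 <- new_child(hap_of(fa), hap_of(pick_founder(r, "F")), r)
    c2 <- new_child(hap_of(fa), hap_of(pick_founder(r, "F")), r)
    rel(c1$id, c2$id, "half_sibling")
  }
  for (k in seq_len(ped$parent_offspring_pairs)) {
    r <- nxt_region()
    fa <- pick_founder(r, "M"); mo <- pick_founder(r, "F")
    ch <- new_child(hap_of(fa), hap_of(mo), r)
    rel(cohort$sample_id[gidx[fa]], ch$id, "parent_offspring")
  }
  latent <- function(region) {   # latent founder, never enters the manifest
    h <- rbind(stats::rbinom(nv, 1, p_reg[, region]),
               stats::rbinom(nv, 1, p_reg[, region]))
    h
  }
  lat_child <- function(f, m) {
    g <- drop_gametes(f, m, variants, map, haplotypes = TRUE)
    g
  }
  for (k in seq_len(ped$consanguineous_pairs)) {
    r <- nxt_region()
    cpl <- lapply(1:3, function(i) list(latent(r), latent(r)))
    sib <- lapply(cpl, function(cp) list(lat_child(cp[[1]], cp[[2]]),
                                         lat_child(cp[[1]], cp[[2]])))
    xm <- lat_child(sib[[1]][[1]], sib[[3]][[1]])
    xf <- lat_child(sib[[2]][[1]], latent(r))
    ym <- lat_child(sib[[1]][[2]], latent(r))
    yf <- lat_child(sib[[2]][[2]], sib[[3]][[2]])
    cx <- new_child(xf, xm, r); cy <- new_child(yf, ym, r)
    rel(cx$id, cy$id, "triple_second_cousin")
  }
  for (k in seq_len(ped$first_cousin_offspring)) {
    r <- nxt_region()
    gf <- latent(r); gm <- latent(r)             # shared grandparents
    s1 <- lat_child(gf, gm); s2 <- lat_child(gf, gm)
    p1 <- lat_child(s1, latent(r)); p2 <- lat_child(s2, latent(r))
    ch <- new_child(p1, p2, r)
    inbred_ids <- c(inbred_ids, ch$id)
  }

  if (length(extra_rows)) {
    extra <- do.call(rbind, extra_rows)
    # children stored in their own (fully selected) boxes
    extra$box <- n_box + (seq_len(nrow(extra)) - 1) %/% cf$box_size + 1
    cohort <- rbind(cohort, extra)
    H1 <- rbind(H1, do.call(rbind, extra_H1))
    H2 <- rbind(H2, do.call(rbind, extra_H2))
  }
  gidx <- which(cohort$genotyped)
  ng <- nrow(H1)
  samples <- cohort[gidx, , drop = FALSE]

  # ---- karyotypes ----
  samples$true_karyotype <- ifelse(samples$sex == "M", "XY", "XX")
  an <- cf$aneuploidy_counts
  assignable <- function(sex, n) {
    cand <- which(samples$sex == sex &
                    samples$true_karyotype %in% c("XX", "XY"))
    sample(cand, min(n, length(cand)))
  }
  for (kt in names(an)) {
    if (an[[kt]] <= 0) next
    sex <- if (kt == "XXY") "M" else "F"
    i <- assignable(sex, an[[kt]])
    samples$true_karyotype[i] <- kt
  }
  # XO: haploid X; XXY: diploid X despite male manifest
  xo <- which(samples$true_karyotype == "XO")
  H2[xo, is_x] <- H1[xo, is_x]
  xxy <- which(samples$true_karyotype == "XXY")
  if (length(xxy)) {
    for (i in xxy) {
      r <- samples$region_idx[i]
      H2[i, is_x] <- stats::rbinom(sum(is_x), 1, p_reg[is_x, r])
    }
  }

  calls <- H1 + H2
  storage.mode(calls) <- "integer"

  # ---- plate layout with fixed-position intentional duplicates ----
  wells <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, 8))
  n_geno <- nrow(samples)
  n_dup <- cf$duplicate_pairs
  # reserve H12 on plates 2..(n_dup+1) for duplicates of D1 on the previous plate
  n_plates <- ceiling((n_geno + n_dup) / 96)
  slot_plate <- rep(seq_len(n_plates), each = 96)
  slot_well <- rep(wells, n_plates)
  reserved <- slot_well == "H12" & slot_plate >= 2 & slot_plate <= n_dup + 1
  open <- which(!reserved)[seq_len(n_geno)]
  samples$plate <- slot_plate[open]
  samples$well <- slot_well[open]

  dup_rows <- list(); dup_calls <- list(); dup_truth <- list()
  for (d in seq_len(n_dup) * (n_dup > 0)) {
    if (d == 0) break
    src <- which(samples$plate == d & samples$well == "D1")
    if (!length(src)) next
    src <- src[1]
    row <- samples[src, , drop = FALSE]
    row$sample_id <- paste0(row$sample_id, "_d")
    row$plate <- d + 1; row$well <- "H12"
    dup_rows[[length(dup_rows) + 1]] <- row
    dup_calls[[length(dup_calls) + 1]] <-
      add_genotype_errors(calls[src, ], cf$dup_error_rate)
    dup_truth[[length(dup_truth) + 1]] <-
      data.frame(id1 = samples$sample_id[src], id2 = row$sample_id,
                 type = "duplicate", stringsAsFactors = FALSE)
  }
  if (length(dup_rows)) {
    samples <- rbind(samples, do.call(rbind, dup_rows))
    calls <- rbind(calls, do.call(rbind, lapply(dup_calls, rbind)))
    relationships <- c(relationships, dup_truth)
  }
  samples$is_duplicate <- grepl("_d$", samples$sample_id)
  samples$batch <- (samples$plate - 1) %/% cf$plates_per_batch + 1
  n_batch <- max(samples$batch)
  samples$array_version <- ifelse(samples$batch <= ceiling(n_batch / 2), 1L, 2L)

  # ---- plate effects: directional het -> hom miscalls ----
  affected <- data.frame(probeset = character(0), variant_id = character(0),
                         plate = integer(0), batch = integer(0),
                         delta = numeric(0))
  pv <- colMeans(calls, na.rm = TRUE) / 2
  for (pe in cf$plate_effects) {
    cand <- which(!is_x & pmin(pv, 1 - pv) > 0.2)
    j <- sample(cand, min(pe$n_probesets, length(cand)))
    on_plate <- which(samples$plate == pe$plate)
    for (jj in j) {
      het <- on_plate[!is.na(calls[on_plate, jj]) & calls[on_plate, jj] == 1L]
      flip <- het[stats::runif(length(het)) < pe$delta]
      calls[flip, jj] <- 2L
    }
    affected <- rbind(affected,
                      data.frame(probeset = variants$probeset[j],
                                 variant_id = variants$id[j],
                                 plate = pe$plate,
                                 batch = unique(samples$batch[on_plate])[1],
                                 delta = pe$delta))
  }

  # ---- missingness ----
  if (cf$missing_rate > 0) {
    nmiss <- stats::rbinom(1, length(calls), cf$missing_rate)
    calls[sample.int(length(calls), nmiss)] <- NA_integer_
  }

  # ---- per-sample intensity metrics ----
  nS <- nrow(samples)
  kt <- samples$true_karyotype
  rn <- function(mu, sd) stats::rnorm(nS, mu, sd)
  f_mu <- c(XX = 0.02, XY = 0.98, XO = 0.95, XO_mosaic = 0.55, XXX = 0.02,
            XXY = 0.5)
  f_sd <- c(XX = 0.04, XY = 0.015, XO = 0.03, XO_mosaic = 0.1, XXX = 0.04,
            XXY = 0.1)
  r_mu <- c(XX = 0.25, XY = 1.0, XO = 0.45, XO_mosaic = 0.4, XXX = 0.18,
            XXY = 0.65)
  r_sd <- c(XX = 0.05, XY = 0.07, XO = 0.06, XO_mosaic = 0.06, XXX = 0.04,
            XXY = 0.07)
  # mosaics modelled as a 70% XO cell fraction: LRR 0.7 x (-0.6), het BAF
  # bands at (1-m)/(2-m) and 1/(2-m)
  l_mu <- c(XX = 0, XY = 0, XO = -0.6, XO_mosaic = -0.42, XXX = 0.4, XXY = 0)
  l_sd <- c(XX = 0.1, XY = 0.1, XO = 0.08, XO_mosaic = 0.08, XXX = 0.08,
            XXY = 0.1)
  sm <- data.frame(sample_id = samples$sample_id,
                   dqc = pmin(stats::rnorm(nS, 0.96, 0.015), 0.999),
                   qc_callrate = pmin(stats::rnorm(nS, 0.995, 0.004), 1),
                   chrx_f = stats::rnorm(nS, f_mu[kt], f_sd[kt]),
                   yx_ratio = pmax(stats::rnorm(nS, r_mu[kt], r_sd[kt]), 0),
                   chrx_lrr = stats::rnorm(nS, l_mu[kt], l_sd[kt]),
                   stringsAsFactors = FALSE)
  sm$chrx_f <- pmin(pmax(sm$chrx_f, -0.2), 1)
  baf_band <- function(k) {
    switch(k,
           XO = numeric(0),
           XO_mosaic = pmin(pmax(c(stats::rnorm(60, 0.27, 0.03),
                                   stats::rnorm(60, 0.73, 0.03)), 0), 1),
           XXX = pmin(pmax(c(stats::rnorm(60, 1 / 3, 0.03),
                             stats::rnorm(60, 2 / 3, 0.03)), 0), 1),
           XY = numeric(0),
           XXY = pmin(pmax(stats::rnorm(80, 0.5, 0.05), 0), 1),
           pmin(pmax(stats::rnorm(120, 0.5, 0.03), 0), 1))
  }
  sm$baf_het <- lapply(kt, baf_band)

  # planted initial-QC failures
  low_dqc <- low_cr <- character(0)
  cand <- which(!samples$is_duplicate)
  if (cf$n_low_dqc > 0) {
    i <- sample(cand, cf$n_low_dqc)
    sm$dqc[i] <- stats::runif(cf$n_low_dqc, 0.72, 0.81)
    low_dqc <- samples$sample_id[i]
    cand <- setdiff(cand, i)
  }
  if (cf$n_low_callrate > 0) {
    i <- sample(cand, cf$n_low_callrate)
    sm$qc_callrate[i] <- stats::runif(cf$n_low_callrate, 0.90, 0.965)
    low_cr <- samples$sample_id[i]
  }
  sm$full_callrate <- rowMeans(!is.na(calls))
  sm$het_fraction <- rowMeans(calls[, !is_x, drop = FALSE] == 1L, na.rm = TRUE)
  sm <- cbind(sm, samples[, c("plate", "well", "batch", "region", "sex")])

  # ---- per-probeset-per-batch clustering metrics ----
  cmgrid <- expand.grid(probeset = variants$probeset,
                        batch = seq_len(n_batch), stringsAsFactors = FALSE)
  ncm <- nrow(cmgrid)
  cm <- data.frame(cmgrid,
                   fld = stats::rnorm(ncm, 16, 2.5),
                   hetso = stats::rnorm(ncm, 1.5, 0.4),
                   homro = stats::rnorm(ncm, 4.5, 0.5),
                   callrate = pmin(stats::rnorm(ncm, 0.995, 0.004), 1))
  if (nrow(affected)) {
    key <- paste(cm$probeset, cm$batch)
    akey <- paste(affected$probeset, affected$batch)
    hit <- key %in% akey
    cm$fld[hit] <- stats::runif(sum(hit), 3, 7)
    cm$hetso[hit] <- stats::runif(sum(hit), -0.2, 0.5)
    cm$homro[hit] <- stats::runif(sum(hit), 0.5, 3)
  }

  # ---- assemble ----
  migrant_ids <- cohort$sample_id[gidx][migrants[migrants <= length(gidx)]]
  # (migrants indexed pre-pedigree; map back to base genotyped members)
  migrant_ids <- cohort$sample_id[which(cohort$genotyped)][migrants]
  boxes <- data.frame(box = seq_len(max(cohort$box)),
                      n = as.vector(table(factor(cohort$box,
                                                 levels = seq_len(max(cohort$box))))))
  sel_by_box <- tapply(cohort$genotyped, factor(cohort$box,
                                                levels = seq_len(max(cohort$box))), sum)
  boxes$n_selected <- as.integer(ifelse(is.na(sel_by_box), 0, sel_by_box))
  boxes$fraction <- ifelse(boxes$n > 0, boxes$n_selected / boxes$n, 0)

  truth <- list(
    relationships = if (length(relationships)) do.call(rbind, relationships)
      else data.frame(id1 = character(0), id2 = character(0), type = character(0)),
    karyotype = stats::setNames(kt, samples$sample_id),
    lrld_intervals = lrld_truth,
    affected_probesets = affected,
    region = stats::setNames(samples$region, samples$sample_id),
    migrants = migrant_ids,
    inbred = inbred_ids,
    boxes = boxes,
    low_dqc = low_dqc, low_callrate = low_cr,
    allele_freq_by_region = p_reg,
    ancestral_freq = p_anc)

  dataset <- genotype_dataset(calls, variants,
                              samples[, c("sample_id", "region", "lat", "long",
                                          "sex", "age", "plate", "well", "box",
                                          "batch", "array_version",
                                          "ascertainment", "is_duplicate")])
  structure(list(dataset = dataset, sample_metrics = sm, cluster_metrics = cm,
                 truth = truth, map = map, cohort = cohort, config = cf),
            class = "qcpop_sim")
}

#' @export
print.qcpop_sim <- function(x, ...) {
  cat("qcpop_sim:", nrow(x$dataset$calls), "genotyped samples (",
      nrow(x$cohort), "cohort members ),", ncol(x$dataset$calls), "variants\n")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes the PLINK1 binary trio plus TSV manifests (`samples.tsv`,
#' `cluster_metrics.tsv`, `intensity.tsv`, `map.tsv`) and the ground-truth
#' labels as `truth.json`. The fileset round-trips losslessly through
#' [read_plink()].
#'
#' @param sim a `qcpop_sim` from [simulate_cohort()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "qcpop_sim"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory: ", dir)
  write_plink(sim$dataset, file.path(dir, "cohort"))
  tsv <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  tsv(sim$dataset$samples, "samples.tsv")
  tsv(sim$cluster_metrics, "cluster_metrics.tsv")
  im <- sim$sample_metrics
  im$baf_het <- vapply(im$baf_het, function(v) paste(round(v, 4), collapse = ","), "")
  tsv(im, "intensity.tsv")
  tsv(sim$map, "map.tsv")
  truth <- sim$truth
  truth$allele_freq_by_region <- NULL
  truth$ancestral_freq <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
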