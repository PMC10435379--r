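#' Genotype dataset container
#'
#' Bundles a sample x variant genotype call matrix with its variant map and
#' sample manifest. Calls count copies of the declared counted allele
#' (`a1` in the variant map): 0, 1, 2 or `NA` for missing. On chrX, males
#' are coded haploid with 0/2 dosage.
#'
#' @param calls integer matrix, samples in rows, variants in columns; values
#'   in \{0, 1, 2, NA\}. Row names are sample ids, column names variant ids.
#' @param variants data.frame with columns `id`, `chrom`, `pos` (bp, 1-based),
#'   `a1` (counted allele), `a2`, and optionally `array_version`, `probeset`.
#' @param samples data.frame with at least a `sample_id` column; typically
#'   also `region`, `sex`, `age`, `plate`, `well`, `box`, `batch`.
#' @return An object of class `genotype_dataset` (a list with elements
#'   `calls`, `variants`, `samples`).
#' @export
genotype_dataset <- function(calls, variants, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(is.data.frame(variants), is.data.frame(samples))
  if (nrow(samples) != nrow(calls))
    stop("sample manifest has ", nrow(samples), " rows but call matrix has ",
         nrow(calls), " rows")
  if (nrow(variants) != ncol(calls))
    stop("variant map has ", nrow(variants), " rows but call matrix has ",
         ncol(calls), " columns")
  need <- c("id", "chrom", "pos", "a1", "a2")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("variant map lacks columns: ", paste(miss, collapse = ", "))
  if (!"sample_id" %in% names(samples)) stop("sample manifest lacks 'sample_id'")
  bad <- calls[!is.na(calls) & !(calls %in% 0:2)]
  if (length(bad)) stop("genotype calls outside {0,1,2,NA}")
  # positions must be sorted within chromosome
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (is.unsorted(p)) stop("variant positions not sorted on chromosome ", ch)
  }
  rownames(calls) <- samples$sample_id
  colnames(calls) <- variants$id
  structure(list(calls = calls, variants = variants, samples = samples),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$calls), "samples x", ncol(x$calls),
      "variants on", length(unique(x$variants$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$calls)

#' Subset a genotype dataset
#'
#' @param x a `genotype_dataset`
#' @param samples,variants logical/integer/character index into rows of the
#'   sample manifest / variant map (default: keep all)
#' @return a `genotype_dataset`
#' @export
subset_dataset <- function(x, samples = NULL, variants = NULL) {
  stopifnot(inherits(x, "genotype_dataset"))
  si <- if (is.null(samples)) seq_len(nrow(x$calls)) else samples
  vi <- if (is.null(variants)) seq_len(ncol(x$calls)) else variants
  if (is.character(si)) si <- match(si, x$samples$sample_id)
  if (is.character(vi)) vi <- match(vi, x$variants$id)
  genotype_dataset(x$calls[si, vi, drop = FALSE],
                   x$variants[vi, , drop = FALSE],
                   x$samples[si, , drop = FALSE])
}

#' Per-variant allele frequency of the counted allele
#'
#' @param x a `genotype_dataset` or a call matrix
#' @return numeric vector of counted-allele frequencies
#' @export
allele_freq <- function(x) {
  g <- if (inherits(x, "genotype_dataset")) x$calls else x
  colMeans(g, na.rm = TRUE) / 2
}

#' Minor allele frequency per variant
#' @param x a `genotype_dataset` or a call matrix
#' @return numeric vector in \[0, 0.5\]
#' @export
maf <- function(x) {
  p <- allele_freq(x)
  pmin(p, 1 - p)
}

# ---- PLINK1 binary I/O ------------------------------------------------------
# The three-file bed/bim/fam format: .bed is SNP-major with the magic bytes
# 0x6c 0x1b 0x01 and 2 bits per genotype (00 = hom A1, 01 = missing,
# 10 = het, 11 = hom A2), four samples per byte, low bits first.

#' Write a genotype dataset as a PLINK1 binary fileset
#'
#' @param x a `genotype_dataset`
#' @param prefix path prefix; `<prefix>.bed`, `.bim` and `.fam` are written
#' @return `prefix`, invisibly
#' @export
write_plink <- function(x, prefix) {
  stopifnot(inherits(x, "genotype_dataset"))
  g <- x$calls
  n <- nrow(g); m <- ncol(g)
  # map dosage of a1 -> 2-bit code
  code <- matrix(3L, n, m)                    # 0 copies of a1 -> hom A2 (11)
  code[!is.na(g) & g == 1L] <- 2L             # het (10)
  code[!is.na(g) & g == 2L] <- 0L             # hom A1 (00)
  code[is.na(g)] <- 1L                        # missing (01)
  npad <- (4 - n %% 4) %% 4
  if (npad) code <- rbind(code, matrix(3L, npad, m))
  nb <- nrow(code) / 4
  idx <- matrix(seq_len(nrow(code)), nrow = 4)
  bytes <- code[idx[1, ], , drop = FALSE] +
    4L * code[idx[2, ], , drop = FALSE] +
    16L * code[idx[3, ], , drop = FALSE] +
    64L * code[idx[4, ], , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)

  v <- x$variants
  cm <- if ("cm" %in% names(v)) v$cm else 0
  utils::write.table(
    data.frame(v$chrom, v$id, cm, v$pos, v$a1, v$a2),
    paste0(prefix, ".bim"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

  s <- x$samples
  sex_code <- if ("sex" %in% names(s)) ifelse(s$sex == "M", 1L, 2L) else 0L
  utils::write.table(
    data.frame(s$sample_id, s$sample_id, 0, 0, sex_code, -9),
    paste0(prefix, ".fam"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a PLINK1 binary fileset into a genotype dataset
#'
#' @param prefix path prefix of the `.bed`/`.bim`/`.fam` trio
#' @param samples optional sample manifest to attach instead of the minimal
#'   one derived from the `.fam` file (must match its order)
#' @return a `genotype_dataset`
#' @export
read_plink <- function(prefix, samples = NULL) {
  bim <- utils::read.table(paste0(prefix, ".bim"), sep = "\t",
                           col.names = c("chrom", "id", "cm", "pos", "a1", "a2"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  fam <- utils::read.table(paste0(prefix, ".fam"), sep = "\t",
                           col.names = c("fid", "sample_id", "pat", "mat",
                                         "sex_code", "pheno"),
                           colClasses = c("character", "character", "character",
                                          "character", "integer", "character"))
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), what = "raw",
                 n = 3 + ceiling(n / 4) * m)
  if (!identical(raw[1:3], as.raw(c(0x6c, 0x1b, 0x01))))
    stop("not a SNP-major PLINK1 .bed file: ", prefix, ".bed")
  body <- as.integer(raw[-(1:3)])
  bpv <- ceiling(n / 4)
  codes <- matrix(0L, 4 * bpv, m)
  b <- matrix(body, bpv, m)
  codes[seq(1, 4 * bpv, by = 4), ] <- b %% 4L
  codes[seq(2, 4 * bpv, by = 4), ] <- (b %/% 4L) %% 4L
  codes[seq(3, 4 * bpv, by = 4), ] <- (b %/% 16L) %% 4L
  codes[seq(4, 4 * bpv, by = 4), ] <- (b %/% 64L) %% 4L
  codes <- codes[seq_len(n), , drop = FALSE]
  g <- matrix(NA_integer_, n, m)
  g[codes == 0L] <- 2L
  g[codes == 2L] <- 1L
  g[codes == 3L] <- 0L
  variants <- bim[, c("id", "chrom", "pos", "a1", "a2", "cm")]
  if (is.null(samples)) {
    samples <- data.frame(sample_id = fam$sample_id,
                          sex = c("M", "F", NA)[pmin(ifelse(fam$sex_code %in% 1:2,
                                                            fam$sex_code, 3L), 3L)],
                          stringsAsFactors = FALSE)
  } else if (!identical(samples$sample_id, fam$sample_id)) {
    stop("supplied manifest does not match .fam sample order")
  }
  genotype_dataset(g, variants, samples)
}
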