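#' Genotype matrix container
#'
#' Allele counts (0/1/2, NA for missing) for individuals x SNPs, plus
#' per-SNP metadata. Counts refer to the `counted` allele of each SNP;
#' the sign of GWAS effects is relative to that orientation.
#'
#' @param counts numeric matrix, rows = individuals (rownames = ids),
#'   columns = SNPs.
#' @param map data frame with columns `snp`, `chrom`, `pos`, `counted`
#'   (one row per column of `counts`); a minimal map is built when `NULL`.
#' @export
genotype_matrix <- function(counts, map = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)))
    stop("counts must have individual ids as rownames")
  if (is.null(map)) {
    snp <- colnames(counts)
    if (is.null(snp)) snp <- paste0("snp", seq_len(ncol(counts)))
    map <- data.frame(snp = snp, chrom = "1", pos = seq_len(ncol(counts)),
                      counted = "A", stringsAsFactors = FALSE)
  }
  stopifnot(nrow(map) == ncol(counts),
            all(c("snp", "chrom", "pos") %in% names(map)))
  if (!"counted" %in% names(map)) map$counted <- "A"
  bad <- counts[!is.na(counts)]
  if (any(!bad %in% c(0, 1, 2)))
    stop("allele counts must be 0, 1, 2 or NA")
  colnames(counts) <- map$snp
  map$chrom <- as.character(map$chrom)
  structure(list(counts = counts, map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype matrix:", nrow(x$counts), "individuals x",
      ncol(x$counts), "SNPs\n")
  invisible(x)
}

#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  if (is.character(j)) j <- match(j, x$map$snp)
  genotype_matrix(x$counts[i, j, drop = FALSE],
                  x$map[j, , drop = FALSE])
}

#' Read genotypes from a TSV matrix
#'
#' Layout: header `id` then one column per SNP; values 0/1/2/NA. SNP
#' metadata (chromosome, position) can be supplied through a map file
#' with columns `snp chrom pos [counted]`; otherwise all SNPs are placed
#' on chromosome 1 in column order.
#'
#' @param path genotype TSV path.
#' @param map_path optional SNP map TSV.
#' @return a [genotype_matrix()].
#' @export
read_genotypes_tsv <- function(path, map_path = NULL) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  stopifnot(names(df)[1L] == "id")
  counts <- as.matrix(df[, -1L, drop = FALSE])
  rownames(counts) <- as.character(df$id)
  map <- if (!is.null(map_path))
    utils::read.delim(map_path, sep = "\t", header = TRUE,
                      colClasses = "character") else NULL
  if (!is.null(map)) map$pos <- as.numeric(map$pos)
  genotype_matrix(counts, map)
}

#' @rdname read_genotypes_tsv
#' @param gm a `genotype_matrix`.
#' @export
write_genotypes_tsv <- function(gm, path, map_path = NULL) {
  df <- data.frame(id = rownames(gm$counts), gm$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(map_path))
    utils::write.table(gm$map, map_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

## Minimal PLINK 1 binary support (SNP-major .bed + .bim/.fam text files).
## Counts refer to the A1 allele (.bim column 5), PLINK's convention.

#' Read a PLINK .bed/.bim/.fam fileset
#'
#' Supports the standard SNP-major binary layout (magic bytes
#' `0x6c 0x1b 0x01`; two bits per genotype: 00 = A1/A1, 10 = het,
#' 11 = A2/A2, 01 = missing). Counts are copies of A1.
#'
#' @param prefix path prefix (without extension).
#' @return a [genotype_matrix()].
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  stopifnot(file.exists(bed), file.exists(bim), file.exists(fam))
  fam_df <- utils::read.table(fam, colClasses = "character")
  bim_df <- utils::read.table(bim, colClasses = "character")
  n <- nrow(fam_df); m <- nrow(bim_df)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3L || raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic bytes)")
  if (raw[3L] != as.raw(0x01))
    stop("only SNP-major .bed files are supported")
  bps <- ceiling(n / 4)  # bytes per SNP
  body <- raw[-(1:3)]
  stopifnot(length(body) == bps * m)
  # decode 2-bit codes: 00->2 copies A1, 10->1, 11->0, 01->NA
  lut <- matrix(NA_real_, 256, 4)
  for (b in 0:255) for (k in 0:3) {
    code <- bitwAnd(bitwShiftR(b, 2L * k), 3L)
    lut[b + 1L, k + 1L] <- c(2, NA, 1, 0)[code + 1L]
  }
  bytes <- matrix(as.integer(body), nrow = bps)
  counts <- matrix(NA_real_, n, m)
  for (k in 1:4) {
    rows <- seq(k, n, by = 4L)
    if (!length(rows)) next
    byte_rows <- (rows + 3L) %/% 4L
    counts[rows, ] <- lut[cbind(as.vector(bytes[byte_rows, , drop = FALSE]) + 1L,
                                k)]
  }
  rownames(counts) <- fam_df[[2L]]
  map <- data.frame(snp = bim_df[[2L]], chrom = bim_df[[1L]],
                    pos = as.numeric(bim_df[[4L]]), counted = bim_df[[5L]],
                    stringsAsFactors = FALSE)
  genotype_matrix(counts, map)
}

#' Write a PLINK .bed/.bim/.fam fileset (SNP-major)
#' @param gm a `genotype_matrix`.
#' @param prefix output path prefix.
#' @export
write_plink <- function(gm, prefix) {
  counts <- gm$counts
  n <- nrow(counts); m <- ncol(counts)
  fam <- data.frame(rownames(counts), rownames(counts), "0", "0", "0", "-9")
  utils::write.table(fam, paste0(prefix, ".fam"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  bim <- data.frame(gm$map$chrom, gm$map$snp, "0", gm$map$pos,
                    gm$map$counted, "B")
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  code <- matrix(1L, n, m)  # 01 = missing
  code[!is.na(counts) & counts == 2] <- 0L
  code[!is.na(counts) & counts == 1] <- 2L
  code[!is.na(counts) & counts == 0] <- 3L
  bps <- ceiling(n / 4)
  pad <- bps * 4L - n
  if (pad) code <- rbind(code, matrix(0L, pad, m))
  k <- seq(1, nrow(code), by = 4L)
  bytes <- code[k, , drop = FALSE] +
    4L * code[k + 1L, , drop = FALSE] +
    16L * code[k + 2L, , drop = FALSE] +
    64L * code[k + 3L, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(prefix)
}

#' Read genotypes from a PLINK prefix or a TSV file
#' @param path PLINK prefix (if `<path>.bed` exists) or genotype TSV.
#' @param map_path optional map TSV (TSV mode only).
#' @export
read_genotypes <- function(path, map_path = NULL) {
  if (file.exists(paste0(path, ".bed"))) read_plink(path)
  else read_genotypes_tsv(path, map_path)
}
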