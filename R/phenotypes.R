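#' Read a categorical phenotype table
#'
#' Tab-separated file with header and columns `id`, `phenotype`.
#' Phenotype classes are integers in `0..K-1` (for horn status the default
#' labels are 0 = polled, 1 = scurs/knobs, 2 = horned); `NA` marks a
#' missing record. Missing records carry no penetrance information but the
#' individuals still conduct pedigree information.
#'
#' @param path file path.
#' @param labels class labels, length K (defines K).
#' @return data frame `id`, `phenotype` (integer or NA) of class
#'   `seg_phenotypes`, with the labels as attribute `labels`.
#' @export
read_phenotypes <- function(path,
                            labels = c("polled", "scurs_knobs", "horned")) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  if (!all(c("id", "phenotype") %in% names(df)))
    stop("phenotype file must have columns 'id' and 'phenotype'")
  ph <- suppressWarnings(as.integer(df$phenotype))
  ph[df$phenotype %in% c("NA", "")] <- NA_integer_
  seg_phenotypes(df$id, ph, labels)
}

#' Construct a phenotype table
#'
#' @param id individual ids.
#' @param phenotype integer classes in `0..K-1`, `NA` for missing.
#' @param labels class labels (length K, K >= 2).
#' @export
seg_phenotypes <- function(id, phenotype,
                           labels = c("polled", "scurs_knobs", "horned")) {
  K <- length(labels)
  stopifnot(K >= 2, length(id) == length(phenotype))
  phenotype <- as.integer(phenotype)
  bad <- !is.na(phenotype) & (phenotype < 0L | phenotype >= K)
  if (any(bad))
    stop("phenotype class out of range 0..", K - 1L, " for id ",
         id[bad][1L], " (value ", phenotype[bad][1L], ")")
  structure(data.frame(id = as.character(id), phenotype = phenotype,
                       stringsAsFactors = FALSE),
            labels = labels, class = c("seg_phenotypes", "data.frame"))
}

#' Write a phenotype table to TSV
#' @param phen a `seg_phenotypes` table.
#' @param path output path.
#' @export
write_phenotypes <- function(phen, path) {
  df <- data.frame(id = phen$id,
                   phenotype = ifelse(is.na(phen$phenotype), "NA",
                                      phen$phenotype))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# phenotype vector aligned to a pedigree's individuals (NA where absent)
align_phenotypes <- function(phen, ped) {
  m <- match(ped$id, phen$id)
  out <- rep(NA_integer_, length(ped$id))
  out[!is.na(m)] <- phen$phenotype[m[!is.na(m)]]
  out
}

#' Mask one sex's phenotype records
#'
#' Used for sex-split analyses: the full pedigree is retained for
#' relationship information, but records of the other sex are set to
#' missing.
#'
#' @param phen a `seg_phenotypes` table.
#' @param ped a `seg_pedigree` providing sex labels.
#' @param keep `"male"` or `"female"`: the sex whose records are kept.
#' @export
mask_phenotypes_by_sex <- function(phen, ped, keep = c("female", "male")) {
  keep <- match.arg(keep)
  sex <- ped$sex[match(phen$id, ped$id)]
  if (all(is.na(sex) | sex == "unknown"))
    stop("pedigree has no sex labels; cannot subset by sex")
  out <- phen
  out$phenotype[is.na(sex) | sex != keep] <- NA_integer_
  attributes(out) <- attributes(phen)
  out
}
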