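#' Construct a pedigree object from a data frame
#'
#' A pedigree is a directed acyclic graph of individuals linked to their
#' sire and dam. Parents named in the `sire`/`dam` columns but absent from
#' the `id` column are inserted as phantom founders; individuals with
#' exactly one recorded parent receive a unique phantom for the missing
#' one, so that every non-founder has two parents (the standard
#' representation for peeling).
#'
#' @param df data frame with columns `id`, `sire`, `dam` and optionally
#'   `sex` (`"male"`/`"female"`/`"unknown"`, or `M`/`F`/`1`/`2`).
#' @param unknown character vector of codes denoting an unknown parent
#'   (default `"0"` and `"NA"`; real `NA` always counts as unknown).
#' @return An object of class `seg_pedigree`: a list with elements
#'   `id` (character), `sire_idx`/`dam_idx` (integer indices into `id`,
#'   `NA` for founders), `sex`, `phantom` (logical), `founders`
#'   (character ids with both parents unknown), and `order`
#'   (a topological permutation, parents before offspring).
#' @export
seg_pedigree <- function(df, unknown = c("0", "NA")) {
  stopifnot(is.data.frame(df), all(c("id", "sire", "dam") %in% names(df)))
  id   <- as.character(df$id)
  sire <- as.character(df$sire)
  dam  <- as.character(df$dam)
  sex  <- if ("sex" %in% names(df)) normalize_sex(df$sex) else
    rep("unknown", nrow(df))
  if (anyDuplicated(id))
    stop("duplicate individual id: ", id[duplicated(id)][1L])
  is_unknown <- function(x) is.na(x) | x %in% unknown
  sire[is_unknown(sire)] <- NA_character_
  dam[is_unknown(dam)]   <- NA_character_
  if (any(bad <- !is.na(sire) & sire == id))
    stop("individual is its own sire: ", id[bad][1L])
  if (any(bad <- !is.na(dam) & dam == id))
    stop("individual is its own dam: ", id[bad][1L])

  # phantom founders: named parents without a record of their own
  phantom <- setdiff(c(sire[!is.na(sire)], dam[!is.na(dam)]), id)
  if (length(phantom)) {
    message("inserting ", length(phantom),
            " phantom founder(s) for parents without records: ",
            paste(utils::head(phantom, 5L), collapse = ", "),
            if (length(phantom) > 5L) ", ..." else "")
    sire_sex <- phantom %in% sire
    id   <- c(id, phantom)
    sex  <- c(sex, ifelse(sire_sex, "male", "female"))
    sire <- c(sire, rep(NA_character_, length(phantom)))
    dam  <- c(dam, rep(NA_character_, length(phantom)))
  }
  is_phantom <- c(rep(FALSE, length(id) - length(phantom)),
                  rep(TRUE, length(phantom)))

  # unique phantom for a single missing parent (other parent recorded)
  half_s <- which(is.na(sire) & !is.na(dam))
  half_d <- which(!is.na(sire) & is.na(dam))
  if (length(half_s) || length(half_d)) {
    new_s <- if (length(half_s))
      paste0("<phantom_sire:", id[half_s], ">") else character(0)
    new_d <- if (length(half_d))
      paste0("<phantom_dam:", id[half_d], ">") else character(0)
    sire[half_s] <- new_s
    dam[half_d]  <- new_d
    id   <- c(id, new_s, new_d)
    sex  <- c(sex, rep("male", length(new_s)), rep("female", length(new_d)))
    sire <- c(sire, rep(NA_character_, length(new_s) + length(new_d)))
    dam  <- c(dam,  rep(NA_character_, length(new_s) + length(new_d)))
    is_phantom <- c(is_phantom, rep(TRUE, length(new_s) + length(new_d)))
  }

  sire_idx <- match(sire, id)
  dam_idx  <- match(dam, id)
  ord <- topological_sort(sire_idx, dam_idx, id)
  ped <- structure(
    list(id = id, sire_idx = sire_idx, dam_idx = dam_idx, sex = sex,
         phantom = is_phantom, founders = id[is.na(sire_idx) & is.na(dam_idx)],
         order = ord),
    class = "seg_pedigree")
  ped
}

normalize_sex <- function(x) {
  x <- tolower(as.character(x))
  out <- rep("unknown", length(x))
  out[x %in% c("m", "male", "1")]   <- "male"
  out[x %in% c("f", "female", "2")] <- "female"
  out
}

# Kahn's algorithm; stable (input order breaks ties). Errors on cycles,
# naming one individual on a cycle.
topological_sort <- function(sire_idx, dam_idx, id) {
  n <- length(id)
  indeg <- integer(n)
  for (p in list(sire_idx, dam_idx)) {
    k <- !is.na(p)
    indeg[k] <- indeg[k] + 1L  # each known parent is one incoming edge
  }
  # children lists
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(sire_idx[i], dam_idx[i]))
      if (!is.na(p)) kids[[p]] <- c(kids[[p]], i)
  }
  queue <- which(indeg == 0L)   # already in input order
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (w in kids[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(ord) < n) {
    on_cycle <- setdiff(seq_len(n), ord)
    stop("pedigree contains a cycle through individual: ", id[on_cycle[1L]])
  }
  ord
}

#' Read a pedigree from a TSV file
#'
#' Expects a tab-separated file with a header; columns `id`, `sire`, `dam`
#' and optionally `sex` (names remappable through `dialect`).
#'
#' @param path file path.
#' @param dialect named list mapping the canonical column roles to the
#'   file's column names, e.g. `list(id = "animal", sire = "father")`.
#' @param unknown codes for an unknown parent (see [seg_pedigree()]).
#' @return a `seg_pedigree`.
#' @export
read_pedigree <- function(path, dialect = list(), unknown = c("0", "NA")) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  cols <- list(id = "id", sire = "sire", dam = "dam", sex = "sex")
  cols[names(dialect)] <- dialect
  for (role in c("id", "sire", "dam"))
    if (!cols[[role]] %in% names(df))
      stop("pedigree file lacks required column '", cols[[role]], "'")
  out <- data.frame(id = df[[cols$id]], sire = df[[cols$sire]],
                    dam = df[[cols$dam]], stringsAsFactors = FALSE)
  if (cols$sex %in% names(df)) out$sex <- df[[cols$sex]]
  seg_pedigree(out, unknown = unknown)
}

#' Write a pedigree to TSV (canonical dialect)
#'
#' Phantom individuals inserted by validation are omitted by default so
#' that read/write round-trips the original rows.
#'
#' @param ped a `seg_pedigree`.
#' @param path output path.
#' @param include_phantoms write phantom founders too?
#' @export
write_pedigree <- function(ped, path, include_phantoms = FALSE) {
  df <- as.data.frame(ped)
  if (!include_phantoms) df <- df[!ped$phantom, , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
as.data.frame.seg_pedigree <- function(x, ...) {
  data.frame(
    id = x$id,
    sire = ifelse(is.na(x$sire_idx), "0", x$id[x$sire_idx]),
    dam  = ifelse(is.na(x$dam_idx),  "0", x$id[x$dam_idx]),
    sex = x$sex, stringsAsFactors = FALSE)
}

#' @export
print.seg_pedigree <- function(x, ...) {
  cat("seg_pedigree:", length(x$id), "individuals (",
      sum(x$phantom), "phantom ),", length(x$founders), "founders\n")
  invisible(x)
}

#' Topological order of a pedigree
#'
#' Returns individual ids ordered so that every parent precedes all of its
#' offspring; ties are broken by input order, so the result is stable
#' across runs.
#'
#' @param ped a `seg_pedigree`.
#' @return character vector of ids, length `length(ped$id)`.
#' @export
topological_order <- function(ped) {
  stopifnot(inherits(ped, "seg_pedigree"))
  ped$id[ped$order]
}
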