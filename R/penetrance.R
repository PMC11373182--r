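#' Construct a penetrance matrix
#'
#' A penetrance matrix gives `P(phenotype class k | genotype class g)` for
#' the three unordered genotype classes of a biallelic locus
#' (0 = aa, 1 = heterozygous, 2 = AA). Rows are phenotype classes, columns
#' genotype classes; every column must sum to 1. Incomplete penetrance is
#' off-diagonal mass.
#'
#' @param mat numeric K x 3 matrix (rows = phenotype classes).
#' @param labels phenotype class labels, length K.
#' @param tol tolerance on column sums.
#' @return matrix of class `penetrance_matrix` with labelled dimnames.
#' @export
penetrance_matrix <- function(mat,
                              labels = c("polled", "scurs_knobs", "horned"),
                              tol = 1e-6) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "double"
  if (ncol(mat) != 3L)
    stop("penetrance matrix must have 3 genotype-class columns")
  if (nrow(mat) != length(labels))
    stop("number of rows must match the number of phenotype labels")
  if (any(mat < -tol) || any(mat > 1 + tol))
    stop("penetrance entries must lie in [0, 1]")
  cs <- colSums(mat)
  bad <- abs(cs - 1) > tol
  if (any(bad))
    stop("penetrance column(s) for genotype class ",
         paste(which(bad) - 1L, collapse = ", "),
         " sum to ", paste(signif(cs[bad], 6), collapse = ", "),
         " (must be 1)")
  dimnames(mat) <- list(labels, c("g0", "g1", "g2"))
  structure(mat, class = c("penetrance_matrix", "matrix", "array"))
}

#' Identity (complete) penetrance
#'
#' Phenotype class equals genotype class with certainty.
#' @param labels phenotype labels (K = 3).
#' @export
penetrance_identity <- function(labels = c("polled", "scurs_knobs",
                                           "horned")) {
  penetrance_matrix(diag(3), labels = labels)
}

#' Standard starting penetrance for horn status
#'
#' The conventional starting point for the horn-status segregation model:
#' aa is always polled, AA always horned, heterozygotes polled with
#' probability 0.25 and scurred/knobbed with probability 0.75.
#' @export
penetrance_start_horn <- function() {
  penetrance_matrix(rbind(c(1, 0.25, 0),
                          c(0, 0.75, 0),
                          c(0, 0.00, 1)))
}

#' Built-in simulation penetrance scenarios
#'
#' Three levels of penetrance used to study how incomplete penetrance
#' degrades the EAC-causal-mutation correlation: `complete` (identity),
#' `moderate` (heterozygotes spread 25/50/25 across classes) and `weak`
#' (heavy overlap between all classes).
#' @return named list of three `penetrance_matrix` objects.
#' @export
penetrance_scenarios <- function() {
  list(
    complete = penetrance_identity(),
    moderate = penetrance_matrix(rbind(c(1, 0.25, 0),
                                       c(0, 0.50, 0),
                                       c(0, 0.25, 1))),
    weak     = penetrance_matrix(rbind(c(0.5, 0.25, 0.0),
                                       c(0.5, 0.50, 0.5),
                                       c(0.0, 0.25, 0.5))))
}

#' Read / write a penetrance matrix as JSON
#'
#' JSON layout: `{"phenotype_labels": [...], "matrix": [[...], ...]}` with
#' rows = phenotype classes and columns = genotype classes 0, 1, 2.
#' Column sums are validated on read.
#'
#' @param path file path.
#' @return a `penetrance_matrix`.
#' @export
read_penetrance <- function(path) {
  stopifnot(file.exists(path))
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (is.null(obj$matrix) || is.null(obj$phenotype_labels))
    stop("penetrance JSON must contain 'phenotype_labels' and 'matrix'")
  penetrance_matrix(obj$matrix, labels = obj$phenotype_labels)
}

#' @rdname read_penetrance
#' @param m a `penetrance_matrix`.
#' @export
write_penetrance <- function(m, path) {
  stopifnot(inherits(m, "penetrance_matrix"))
  jsonlite::write_json(
    list(phenotype_labels = rownames(m),
         matrix = unclass(m)),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @export
print.penetrance_matrix <- function(x, ...) {
  cat("penetrance matrix (rows = phenotype classes, cols = genotype",
      "classes 0/1/2):\n")
  print(unclass(round(x, 4)))
  invisible(x)
}
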