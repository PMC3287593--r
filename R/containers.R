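# Matrix containers used throughout the pipeline. Both are thin S3 wrappers
# around a numeric matrix plus a coordinate annotation data.frame, in the
# spirit of limma's EList: plain enough to poke at, validated enough to trust.

#' Dosage (aCGH log-ratio) matrix
#'
#' @param values numeric matrix, rows = markers, columns = clones, in log10
#'   ratio units (RH over recipient control).
#' @param markers data.frame with columns `id`, `chrom`, `pos` and `class`
#'   (`"autosome"`/`"sex"`), one row per matrix row.
#' @param state processing state: `"raw"`, `"smoothed"`, `"normalized"` or
#'   `"binned"`.
#' @return an object of class `dosage_matrix`.
#' @export
dosage_matrix <- function(values, markers,
                          state = c("raw", "smoothed", "normalized", "binned")) {
  state <- match.arg(state)
  values <- as.matrix(values)
  stopifnot(is.numeric(values), is.data.frame(markers),
            all(c("id", "chrom", "pos", "class") %in% names(markers)),
            nrow(values) == nrow(markers))
  if (anyDuplicated(markers$id)) stop("duplicated marker ids")
  if (state == "binned" && !all(values %in% c(0, 1)))
    stop("binned dosage values must be 0/1")
  rownames(values) <- markers$id
  structure(list(values = values, markers = markers, state = state),
            class = "dosage_matrix")
}

#' Expression log-ratio matrix
#'
#' @param values numeric matrix, rows = genes, columns = clones, log10
#'   expression ratio (RH over recipient control).
#' @param genes data.frame with columns `id`, `chrom`, `start`, `end`.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, genes) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), is.data.frame(genes),
            all(c("id", "chrom", "start", "end") %in% names(genes)),
            nrow(values) == nrow(genes))
  if (anyDuplicated(genes$id)) stop("duplicated gene ids")
  rownames(values) <- genes$id
  structure(list(values = values, genes = genes), class = "expression_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat("dosage_matrix [", x$state, "]: ", nrow(x$values), " markers x ",
      ncol(x$values), " clones\n", sep = "")
  invisible(x)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix: ", nrow(x$values), " genes x ",
      ncol(x$values), " clones\n", sep = "")
  invisible(x)
}

#' @export
dim.dosage_matrix <- function(x) dim(x$values)

#' @export
dim.expression_matrix <- function(x) dim(x$values)
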