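# Tab-separated interchange formats. Matrices travel as TSV with leading
# coordinate columns; intervals travel as BED (0-based, half-open).

matrix_schema <- list(
  dosage = c("id", "chrom", "pos", "class"),
  expression = c("id", "chrom", "start", "end"))

#' Read an expression or dosage matrix from tab-separated text
#'
#' Expected layout: a header row, leading annotation columns (`id`,
#' `chrom`, `pos`, `class` for dosage; `id`, `chrom`, `start`, `end` for
#' expression) and one numeric column per clone. `NA` cells become missing
#' values; their count is reported via a message.
#'
#' @param path file path.
#' @param kind `"expression"` or `"dosage"`.
#' @param state processing state to stamp on a dosage matrix.
#' @return an `expression_matrix` or `dosage_matrix`.
#' @export
read_matrix <- function(path, kind = c("expression", "dosage"),
                        state = "raw") {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- matrix_schema[[kind]]
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L)
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  ann <- df[, need, drop = FALSE]
  for (cc in intersect(c("pos", "start", "end"), names(ann)))
    ann[[cc]] <- as.numeric(ann[[cc]])
  vals <- as.matrix(df[, setdiff(names(df), need), drop = FALSE])
  storage.mode(vals) <- "double"
  n_na <- sum(is.na(vals))
  if (n_na > 0L) message(n_na, " missing value(s) in ", path)
  if (kind == "dosage") dosage_matrix(vals, ann, state = state)
  else expression_matrix(vals, ann)
}

# Atomic write: assemble in a sibling temp file, then rename into place.
write_atomic <- function(lines_fun, path) {
  tmp <- tempfile(tmpdir = dirname(path))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  lines_fun(tmp)
  if (!file.rename(tmp, path)) stop("could not write ", path)
  invisible(path)
}

#' Write a matrix container as tab-separated text
#'
#' Values are printed with 15 significant digits so a write/read round trip
#' reproduces them to well past 10 significant digits.
#'
#' @param x an `expression_matrix` or `dosage_matrix`.
#' @param path output path (written atomically).
#' @return the path, invisibly.
#' @export
write_matrix <- function(x, path) {
  if (inherits(x, "dosage_matrix")) {
    ann <- x$markers[, matrix_schema$dosage]
  } else if (inherits(x, "expression_matrix")) {
    ann <- x$genes[, matrix_schema$expression]
  } else stop("not a matrix container")
  df <- cbind(ann, as.data.frame(signif(x$values, 15), check.names = FALSE))
  write_atomic(function(tmp)
    utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE),
    path)
}

#' Read a BED file (0-based, half-open intervals)
#'
#' @param path file path.
#' @return data.frame with columns `chrom`, `start`, `end` and, if present,
#'   `id`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED file needs at least 3 columns: ", path)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4L) names(df)[4L] <- "id"
  df
}

#' Write intervals as BED (0-based, half-open)
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and optionally
#'   an id-like fourth column (`id`, `block` or `name`).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- intervals[, c("chrom", "start", "end")]
  idcol <- intersect(c("id", "block", "name"), names(intervals))
  if (length(idcol) > 0L) cols$name <- intervals[[idcol[1L]]]
  write_atomic(function(tmp)
    utils::write.table(cols, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE),
    path)
}

#' Average technical replicate arrays on the log scale
#'
#' Replicate columns are identified by the trailing suffixes `a` and `b`
#' on a shared clone stem (e.g. `clone01a`/`clone01b`); each pair is
#' averaged arithmetically on the log scale. Columns without a partner are
#' kept as-is with a warning.
#'
#' @param expr an `expression_matrix` with replicate-suffixed columns.
#' @return an `expression_matrix` with one column per clone; attribute
#'   `replicate_correlation` holds the per-pair Pearson correlation.
#' @export
average_replicates <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  cn <- colnames(expr$values)
  stem <- sub("[ab]$", "", cn)
  suffix <- substring(cn, nchar(cn))
  out <- list(); cors <- numeric(0)
  for (s in unique(stem)) {
    idx <- which(stem == s)
    if (length(idx) == 2L && setequal(suffix[idx], c("a", "b"))) {
      a <- expr$values[, idx[suffix[idx] == "a"]]
      b <- expr$values[, idx[suffix[idx] == "b"]]
      out[[s]] <- (a + b) / 2
      cors[s] <- stats::cor(a, b)
    } else {
      warning("no replicate pair for column stem '", s, "'; kept as-is")
      out[[s]] <- expr$values[, idx[1L]]
    }
  }
  vals <- do.call(cbind, out)
  colnames(vals) <- names(out)
  res <- expression_matrix(vals, expr$genes)
  attr(res, "replicate_correlation") <- cors
  res
}

#' Write a ceQTL result table
#' @param records a `ceqtl_table`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_ceqtl_table <- function(records, path) {
  write_atomic(function(tmp)
    utils::write.table(as.data.frame(records), tmp, sep = "\t",
                       quote = FALSE, row.names = FALSE),
    path)
}

#' Read a ceQTL result table
#' @param path file path.
#' @return a `ceqtl_table` data.frame.
#' @export
read_ceqtl_table <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  class(df) <- c("ceqtl_table", "data.frame")
  df
}
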