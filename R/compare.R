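#' Gene-gene Pearson correlation matrix of an expression dataset
#'
#' @param expr an `expression_matrix` (or plain genes x samples matrix).
#' @return symmetric correlation matrix with unit diagonal; genes with zero
#'   variance are excluded and listed in attribute `dropped_genes`.
#' @export
correlation_matrix <- function(expr) {
  v <- if (inherits(expr, "expression_matrix")) expr$values else as.matrix(expr)
  sds <- apply(v, 1L, stats::sd)
  dropped <- rownames(v)[sds == 0 | !is.finite(sds)]
  keep <- sds > 0 & is.finite(sds)
  if (!any(keep)) stop("all genes have zero variance")
  cm <- stats::cor(t(v[keep, , drop = FALSE]))
  attr(cm, "dropped_genes") <- dropped
  cm
}

#' Frobenius distance between two correlation matrices
#'
#' `sqrt(sum((A - B)^2))` over matrices aligned on the same gene list.
#'
#' @param a,b correlation matrices with identical dimnames.
#' @return nonnegative scalar distance.
#' @export
frobenius_distance <- function(a, b) {
  if (!identical(dim(a), dim(b)) || !identical(rownames(a), rownames(b)))
    stop("gene lists differ: ",
         paste(utils::head(c(setdiff(rownames(a), rownames(b)),
                             setdiff(rownames(b), rownames(a))), 5L),
               collapse = ", "))
  sqrt(sum((a - b)^2))
}

#' Permutation test of correlation-structure similarity
#'
#' Compares the observed Frobenius distance between the dataset's
#' correlation matrix and a reference correlation matrix against a null in
#' which gene identities of the expression matrix are permuted. Permuting
#' gene labels leaves the multiset of pairwise correlations intact (the
#' permuted correlation matrix is a symmetric row/column permutation of
#' the original), so the null preserves correlation structure while
#' destroying gene identity. `P = (# permuted distances < observed) /
#' n_perm` (strictly less).
#'
#' @param expr an `expression_matrix` whose genes cover the reference's
#'   gene list.
#' @param reference correlation matrix (genes x genes, dimnames set).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list of class `distance_result`: `observed`, `null` (vector of
#'   permuted distances), `n_perm`, `p.value`, `p_floor`.
#' @export
permutation_distance_test <- function(expr, reference, n_perm = 10000,
                                      seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  cm <- correlation_matrix(expr)
  shared <- intersect(rownames(cm), rownames(reference))
  if (length(shared) < 2L) stop("fewer than 2 shared genes with the reference")
  cm <- cm[shared, shared]
  ref <- reference[shared, shared]
  observed <- frobenius_distance(cm, ref)
  set.seed(seed)
  n <- length(shared)
  null <- vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    # gene-label permutation: correlation structure preserved exactly
    pm <- cm[p, p, drop = FALSE]
    dimnames(pm) <- dimnames(cm)
    frobenius_distance(pm, ref)
  }, numeric(1))
  structure(list(observed = observed, null = null, n_perm = n_perm,
                 p.value = sum(null < observed) / n_perm,
                 p_floor = 1 / n_perm),
            class = "distance_result")
}

#' @export
print.distance_result <- function(x, ...) {
  cat("distance_result: observed", signif(x$observed, 5), "; P =",
      format(x$p.value), "over", x$n_perm, "permutations\n")
  invisible(x)
}
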