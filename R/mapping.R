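#' Fit the linear dosage model for one gene-marker pair
#'
#' Ordinary least squares fit of `y = mu + alpha * x` where `y` is the
#' expression log10 ratio across clones and `x` the dosage log10 ratio at
#' one marker. The fit is compared with the reduced model `y = mu` by an
#' F statistic with 1 numerator degree of freedom:
#' `F = (RSS_reduced - RSS_full) / (RSS_full / (n - 2))`.
#' A perfect fit (`RSS_full = 0`) reports `F = Inf`. Clones missing either
#' value are dropped pairwise.
#'
#' @param y expression values over clones.
#' @param x dosage values over clones (same length).
#' @return list of class `linear_fit` with `mu`, `alpha`, `F`, `n`,
#'   `rss_full`, `rss_reduced`.
#' @export
fit_dosage_model <- function(y, x) {
  stopifnot(length(y) == length(x))
  keep <- is.finite(y) & is.finite(x)
  y <- y[keep]; x <- x[keep]
  n <- length(y)
  if (n < 3L) stop("need at least 3 complete clone pairs, got ", n)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("degenerate regressor: dosage is constant across clones")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  alpha <- sxy / sxx
  mu <- mean(y) - alpha * mean(x)
  rss_full <- syy - alpha * sxy
  rss_full <- max(rss_full, 0)  # guard tiny negative round-off
  f <- if (rss_full <= .Machine$double.eps * syy)
    if (syy == 0) 0 else Inf
  else (syy - rss_full) / (rss_full / (n - 2L))
  structure(list(mu = mu, alpha = alpha, F = f, n = n,
                 rss_full = rss_full, rss_reduced = syy),
            class = "linear_fit")
}

# Vectorized OLS/F of one expression vector against many markers.
# X: markers x clones matrix without missing values, y: clone vector.
# Returns data.frame(alpha, F, sxx). Constant markers get NA (skipped).
fit_gene_vs_markers <- function(y, X) {
  if (anyNA(y) || anyNA(X)) {  # slow path: pairwise-complete per marker
    res <- apply(X, 1L, function(x) {
      tryCatch({
        f <- fit_dosage_model(y, x)
        c(f$alpha, f$F, sum((x - mean(x, na.rm = TRUE))^2, na.rm = TRUE))
      }, error = function(e) c(NA_real_, NA_real_, NA_real_))
    })
    return(data.frame(alpha = res[1, ], F = res[2, ], sxx = res[3, ]))
  }
  n <- length(y)
  yc <- y - mean(y)
  syy <- sum(yc^2)
  xm <- rowMeans(X)
  sxx <- rowSums(X^2) - n * xm^2
  sxy <- as.vector(X %*% yc)
  alpha <- sxy / sxx
  rss <- pmax(syy - alpha * sxy, 0)
  f <- (syy - rss) / (rss / (n - 2L))
  f[rss <= .Machine$double.eps * syy] <- if (syy == 0) 0 else Inf
  const <- sxx <= .Machine$double.eps * pmax(rowSums(X^2), 1)
  alpha[const] <- NA_real_; f[const] <- NA_real_
  data.frame(alpha = alpha, F = f, sxx = sxx)
}

#' Build a pooled permutation null of F statistics
#'
#' For each gene and each permutation round the clone labels of the
#' expression vector are reshuffled (dosage untouched, so the correlation
#' structure of markers is retained) and the F statistic recomputed for
#' every evaluated gene-marker pair. All permuted F values are pooled into
#' one empirical null distribution.
#'
#' @param expr an `expression_matrix`.
#' @param dosage a `dosage_matrix` with the same clone columns.
#' @param n_perm permutations per pair (>= 1); 5 suffices because pooling
#'   across pairs multiplies the effective null size.
#' @param seed RNG seed.
#' @param pairs optional list mapping gene id -> integer marker row indices
#'   to evaluate; default is the full gene x marker cross product.
#' @return object of class `null_distribution`: sorted numeric vector field
#'   `values`, plus `count`, `n_perm`, `seed`.
#' @export
build_null <- function(expr, dosage, n_perm = 5, seed = 1L, pairs = NULL) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(dosage, "dosage_matrix"))
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!identical(colnames(expr$values), colnames(dosage$values)))
    stop("expression and dosage clone columns differ")
  set.seed(seed)
  n <- ncol(expr$values)
  out <- vector("list", nrow(expr$values))
  for (gi in seq_len(nrow(expr$values))) {
    y <- expr$values[gi, ]
    midx <- if (is.null(pairs)) seq_len(nrow(dosage$values)) else
      pairs[[rownames(expr$values)[gi]]]
    if (length(midx) == 0L) next
    X <- dosage$values[midx, , drop = FALSE]
    fs <- matrix(NA_real_, length(midx), n_perm)
    for (p in seq_len(n_perm)) {
      yp <- y[sample.int(n)]
      fs[, p] <- fit_gene_vs_markers(yp, X)$F
    }
    out[[gi]] <- as.vector(fs)
  }
  vals <- unlist(out)
  vals <- vals[!is.na(vals)]
  structure(list(values = sort(vals), count = length(vals),
                 n_perm = n_perm, seed = seed),
            class = "null_distribution")
}

#' Empirical P value against a pooled null
#'
#' `P = (# null values strictly greater than F) / count`; ties count as not
#' greater. When `P = 0` the resolution floor `1 / count` is attached as
#' the attribute `p_floor`.
#'
#' @param f_obs observed F statistic(s).
#' @param null a `null_distribution`.
#' @return numeric vector of P values with attribute `p_floor`.
#' @export
empirical_p <- function(f_obs, null) {
  stopifnot(inherits(null, "null_distribution"))
  if (null$count == 0L) stop("empty null distribution")
  # findInterval counts null values <= f_obs on the sorted null
  p <- (null$count - findInterval(f_obs, null$values)) / null$count
  p[is.infinite(f_obs)] <- 0
  attr(p, "p_floor") <- 1 / null$count
  p
}

#' Classify a gene-marker pair as cis or trans
#'
#' Distance is 0 if the marker lies inside the gene interval, otherwise the
#' bp gap to the nearer gene boundary; pairs on different chromosomes have
#' infinite distance. A pair is cis iff same chromosome and distance <=
#' `radius`.
#'
#' @param gene one-row data.frame (or list) with `chrom`, `start`, `end`.
#' @param marker one-row data.frame (or list) with `chrom`, `pos`.
#' @param radius cis radius in bp.
#' @return list with `class` (`"cis"`/`"trans"`) and `distance`.
#' @export
classify_pair <- function(gene, marker, radius = 5e6) {
  if (gene$chrom != marker$chrom)
    return(list(class = "trans", distance = Inf))
  d <- point_interval_distance(marker$pos, gene$start, gene$end)
  list(class = if (d <= radius) "cis" else "trans", distance = d)
}

#' Benjamini-Hochberg q-values computed separately per class
#'
#' Cis and trans pairs test different hypothesis families, so the step-up
#' adjustment is applied independently within each class.
#'
#' @param records a ceQTL data.frame with columns `P` and `class`.
#' @return the records with a `q` column added.
#' @export
fdr_by_class <- function(records) {
  stopifnot(is.data.frame(records), all(c("P", "class") %in% names(records)))
  records$q <- NA_real_
  for (cl in unique(records$class)) {
    idx <- which(records$class == cl)
    records$q[idx] <- stats::p.adjust(records$P[idx], method = "BH")
  }
  records
}

#' Keep only markers that vary in copy number
#'
#' Discards markers for which no sample exceeds the gain threshold or falls
#' below the loss threshold; used before cis-only regression on datasets
#' (such as tumor panels) where much of the genome is copy-neutral.
#' Thresholds are in the same log base as the matrix (defaults assume
#' log10; the conventional log2(3/2)/log2(1/2) cutoffs translate to
#' log10(3/2) and log10(1/2)).
#'
#' @param dosage a `dosage_matrix`.
#' @param gain_threshold keep marker if any sample value is above this.
#' @param loss_threshold keep marker if any sample value is below this.
#' @return the filtered `dosage_matrix` (warning if nothing survives).
#' @export
filter_variable_markers <- function(dosage, gain_threshold = log10(3 / 2),
                                    loss_threshold = log10(1 / 2)) {
  stopifnot(inherits(dosage, "dosage_matrix"))
  keep <- apply(dosage$values, 1L, function(v)
    any(v > gain_threshold, na.rm = TRUE) || any(v < loss_threshold, na.rm = TRUE))
  if (!any(keep)) {
    warning("no marker shows copy-number change beyond the thresholds")
  }
  out <- dosage
  out$values <- dosage$values[keep, , drop = FALSE]
  out$markers <- dosage$markers[keep, , drop = FALSE]
  out
}

#' Find association peaks along chromosomes for one gene
#'
#' Local maxima of the -log10 P profile over marker position, one profile
#' per chromosome. Two maxima count as distinct peaks only when the profile
#' drops by at least `support_drop` (in -log10 P units, relative to the
#' lower summit) somewhere between them. Each peak is annotated with its
#' support interval: the outermost contiguous markers within `support_drop`
#' of the peak height.
#'
#' @param records data.frame for one gene with columns `marker`,
#'   `marker_chrom`, `marker_pos`, `P`.
#' @param support_drop required drop in -log10 P between distinct peaks.
#' @param p_floor value substituted for P = 0 before taking logs.
#' @return data.frame of peaks: marker, chrom, pos, neg_log10_p,
#'   support_start, support_end.
#' @export
find_peaks <- function(records, support_drop = 2, p_floor = NULL) {
  stopifnot(is.data.frame(records),
            all(c("marker", "marker_chrom", "marker_pos", "P") %in% names(records)))
  if (is.null(p_floor)) p_floor <- min(c(records$P[records$P > 0], 1e-12)) / 10
  out <- list()
  for (ch in unique(records$marker_chrom)) {
    r <- records[records$marker_chrom == ch, ]
    r <- r[order(r$marker_pos), ]
    h <- -log10(pmax(r$P, p_floor))
    m <- length(h)
    is_max <- vapply(seq_len(m), function(i) {
      (i == 1L || h[i] >= h[i - 1L]) && (i == m || h[i] >= h[i + 1L])
    }, logical(1))
    cand <- which(is_max)
    if (length(cand) > 1L) {  # collapse flat plateaus to their first marker
      keep <- c(TRUE, !(diff(cand) == 1L &
                          h[cand[-1L]] == h[cand[-length(cand)]]))
      cand <- cand[keep]
    }
    cand <- cand[order(h[cand], decreasing = TRUE)]
    accepted <- integer(0)
    for (i in cand) {
      ok <- TRUE
      for (j in accepted) {
        lo <- min(i, j); hi <- max(i, j)
        valley <- min(h[lo:hi])
        if (min(h[i], h[j]) - valley < support_drop) { ok <- FALSE; break }
      }
      if (ok) accepted <- c(accepted, i)
    }
    for (i in sort(accepted)) {
      lo <- i; hi <- i
      while (lo > 1L && h[lo - 1L] >= h[i] - support_drop) lo <- lo - 1L
      while (hi < m && h[hi + 1L] >= h[i] - support_drop) hi <- hi + 1L
      out[[length(out) + 1L]] <- data.frame(
        marker = r$marker[i], chrom = ch, pos = r$marker_pos[i],
        neg_log10_p = h[i], support_start = r$marker_pos[lo],
        support_end = r$marker_pos[hi], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(marker = character(0), chrom = character(0),
                      pos = numeric(0), neg_log10_p = numeric(0),
                      support_start = numeric(0), support_end = numeric(0)))
  do.call(rbind, out)
}

#' Map ceQTLs: dosage model, permutation null, cis/trans FDR
#'
#' For each gene, evaluates the dosage model against a marker set
#' consisting of all markers within `radius` of the gene (the cis
#' candidates) plus every `trans_stride`-th marker genome-wide; the full
#' cross product of the study design is cluster-scale, so the stride keeps
#' desk runs tractable while still tiling the genome. P values are
#' calibrated against a pooled permutation null built from the same pairs,
#' and Benjamini-Hochberg q-values are assigned separately to the cis and
#' trans families.
#'
#' @param expr an `expression_matrix` (clone columns matching `dosage`).
#' @param dosage a normalized (or binned) `dosage_matrix`.
#' @param radius cis radius in bp.
#' @param n_perm permutation rounds per pair.
#' @param trans_stride take every k-th marker as a trans candidate; 1
#'   evaluates the full cross product.
#' @param seed RNG seed for the permutation null.
#' @return data.frame of class `ceqtl_table`, one row per evaluated pair:
#'   gene, marker, chromosomes/positions, `alpha`, `F`, `P`, `distance`,
#'   `class`, `q`, `n`. Pairs with a constant regressor are skipped; their
#'   count is in attribute `n_skipped_constant`, the null size in attribute
#'   `null_count`.
#' @export
map_ceqtl <- function(expr, dosage, radius = 5e6, n_perm = 5,
                      trans_stride = 10, seed = 1L) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(dosage, "dosage_matrix"))
  if (!identical(colnames(expr$values), colnames(dosage$values)))
    stop("expression and dosage clone columns differ")
  genes <- expr$genes
  m <- dosage$markers
  stride_idx <- seq(1L, nrow(m), by = trans_stride)

  pairs <- vector("list", nrow(genes))
  names(pairs) <- genes$id
  for (gi in seq_len(nrow(genes))) {
    same <- which(m$chrom == genes$chrom[gi])
    cis_idx <- same[point_interval_distance(m$pos[same], genes$start[gi],
                                            genes$end[gi]) <= radius]
    pairs[[gi]] <- sort(unique(c(cis_idx, stride_idx)))
  }

  recs <- vector("list", nrow(genes))
  n_skipped <- 0L
  for (gi in seq_len(nrow(genes))) {
    y <- expr$values[gi, ]
    midx <- pairs[[gi]]
    fit <- fit_gene_vs_markers(y, dosage$values[midx, , drop = FALSE])
    bad <- is.na(fit$F)
    n_skipped <- n_skipped + sum(bad)
    midx <- midx[!bad]; fit <- fit[!bad, , drop = FALSE]
    if (length(midx) == 0L) next
    d <- ifelse(m$chrom[midx] == genes$chrom[gi],
                point_interval_distance(m$pos[midx], genes$start[gi],
                                        genes$end[gi]), Inf)
    recs[[gi]] <- data.frame(
      gene = genes$id[gi], marker = m$id[midx],
      gene_chrom = genes$chrom[gi], gene_start = genes$start[gi],
      gene_end = genes$end[gi], marker_chrom = m$chrom[midx],
      marker_pos = m$pos[midx], alpha = fit$alpha, F = fit$F,
      distance = d, n = length(y), stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  if (is.null(records) || nrow(records) == 0L)
    stop("no evaluable gene-marker pairs")
  null <- build_null(expr, dosage, n_perm = n_perm, seed = seed, pairs = pairs)
  records$P <- as.numeric(empirical_p(records$F, null))
  records$class <- ifelse(is.finite(records$distance) &
                            records$distance <= radius, "cis", "trans")
  records <- fdr_by_class(records)
  attr(records, "n_skipped_constant") <- n_skipped
  attr(records, "null_count") <- null$count
  attr(records, "p_floor") <- 1 / null$count
  class(records) <- c("ceqtl_table", "data.frame")
  records
}
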