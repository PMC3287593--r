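#' Sliding-window smoothing of aCGH log-ratios
#'
#' Each marker value is replaced by the mean of a centered window of
#' adjacent markers on the same chromosome (for even widths the window
#' extends one marker further to the left). Windows are truncated at
#' chromosome ends and never span chromosomes.
#'
#' @param raw a `dosage_matrix` (any state; typically raw).
#' @param window window width in markers (>= 1); 10 is the conventional
#'   choice for dense aCGH panels.
#' @return a `dosage_matrix` with state `"smoothed"`.
#' @export
sliding_window_smooth <- function(raw, window = 10) {
  stopifnot(inherits(raw, "dosage_matrix"), window >= 1)
  window <- as.integer(window)
  out <- raw$values
  left <- window %/% 2L
  right <- window - 1L - left
  for (ch in unique(raw$markers$chrom)) {
    idx <- which(raw$markers$chrom == ch)
    m <- length(idx)
    v <- raw$values[idx, , drop = FALSE]
    if (window > m) {
      warning("window (", window, ") exceeds marker count (", m, ") on ", ch,
              "; using whole-chromosome mean")
      out[idx, ] <- matrix(colMeans(v), m, ncol(v), byrow = TRUE)
      next
    }
    cs <- apply(v, 2L, cumsum)
    cs <- rbind(0, cs)
    lo <- pmax(seq_len(m) - left, 1L)
    hi <- pmin(seq_len(m) + right, m)
    out[idx, ] <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) /
      (hi - lo + 1L)
  }
  dosage_matrix(out, raw$markers, state = "smoothed")
}

#' Locate the two modes of a bimodal log-ratio distribution
#'
#' Mode finding uses a Gaussian kernel density estimate with a Silverman
#' bandwidth computed from the sample standard deviation (the IQR variant
#' collapses when one mode dominates). The two candidate modes are the two
#' highest local density maxima separated by at least `min_sep`; each center
#' is then refined by mean-shift iteration, which converges to the exact
#' KDE mode. Component membership for the 95th-percentile threshold is
#' split at the density minimum between the two centers.
#'
#' @param values numeric vector of log10 ratios (>= 100 values recommended).
#' @param min_sep minimum separation (log10 units) between modes.
#' @param weight_floor minimum fraction of values in the upper component;
#'   below this the distribution is declared unimodal.
#' @param bw kernel bandwidth; default `0.9 * sd(values) * n^(-1/5)`.
#' @return an object of class `mode_estimate` with fields `mode1_center`,
#'   `mode2_center`, `mode1_p95`, `split` (component boundary), `weights`
#'   and `bw`.
#' @export
fit_bimodal_modes <- function(values, min_sep = 0.05, weight_floor = 0.01,
                              bw = NULL) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) stop("no gain detected: too few values")
  s <- stats::sd(values)
  if (s == 0) stop("no gain detected: values have zero spread")
  if (is.null(bw)) bw <- 0.9 * s * n^(-1 / 5)
  d <- stats::density(values, bw = bw, n = 1024L)
  ymax <- which(diff(sign(diff(d$y))) < 0) + 1L  # local maxima of KDE
  if (length(ymax) < 1L) stop("no gain detected: no density mode found")
  peaks <- ymax[order(d$y[ymax], decreasing = TRUE)]
  m1 <- d$x[peaks[1L]]
  m2 <- NA_real_
  for (p in peaks[-1L]) {
    if (abs(d$x[p] - m1) >= min_sep) { m2 <- d$x[p]; break }
  }
  if (is.na(m2)) stop("no gain detected: distribution is unimodal")

  mean_shift <- function(m) {
    for (i in 1:100) {
      w <- stats::dnorm((values - m) / bw)
      if (sum(w) == 0) break
      m_new <- sum(w * values) / sum(w)
      if (abs(m_new - m) < 1e-12) return(m_new)
      m <- m_new
    }
    m
  }
  c1 <- mean_shift(m1); c2 <- mean_shift(m2)
  lo <- min(c1, c2); hi <- max(c1, c2)

  # component boundary: density minimum between the two centers
  grid <- seq(lo, hi, length.out = 512L)
  dens <- stats::approx(d$x, d$y, xout = grid)$y
  split <- grid[which.min(dens)]
  w2 <- mean(values > split)
  if (w2 < weight_floor || w2 > 1 - weight_floor)
    stop("no gain detected: second mode weight ", signif(min(w2, 1 - w2), 3),
         " below floor ", weight_floor)
  lower <- values[values <= split]
  structure(list(mode1_center = lo, mode2_center = hi,
                 mode1_p95 = unname(stats::quantile(lower, 0.95)),
                 split = split, weights = c(1 - w2, w2), bw = bw, n = n),
            class = "mode_estimate")
}

#' @export
print.mode_estimate <- function(x, ...) {
  cat("mode_estimate: centers (", signif(x$mode1_center, 4), ", ",
      signif(x$mode2_center, 4), "), first-mode p95 ",
      signif(x$mode1_p95, 4), "\n", sep = "")
  invisible(x)
}

# Normalization target on the log10 scale for a chromosome class: one extra
# copy on a diploid autosome is 3/2; on a haploid (male) sex chromosome 2/1.
norm_target <- function(class) {
  ifelse(class == "sex", log10(2), log10(3 / 2))
}

#' Normalize dosage by mode centering and scaling
#'
#' Applies the affine map `v -> (v - mode1) * target / (mode2 - mode1)` so
#' that the lower mode (no extra copy, ratio 2/2) sits at 0 and the upper
#' mode at log10(3/2) for autosomal markers or log10(2/1) for
#' sex-chromosome markers.
#'
#' @param smoothed a `dosage_matrix` (typically smoothed).
#' @param modes a `mode_estimate` fitted to the pooled values of the markers
#'   being normalized.
#' @param eps minimum mode separation; smaller separations are an error.
#' @return a `dosage_matrix` with state `"normalized"`; the field
#'   `norm_modes` holds the mode estimate mapped onto the normalized scale
#'   (used by [call_retention()] for its threshold).
#' @export
normalize_dosage <- function(smoothed, modes, eps = 1e-6) {
  stopifnot(inherits(smoothed, "dosage_matrix"), inherits(modes, "mode_estimate"))
  sep <- modes$mode2_center - modes$mode1_center
  if (sep < eps) stop("degenerate mode separation: ", signif(sep, 3))
  target <- norm_target(smoothed$markers$class)
  scale <- target / sep
  vals <- (smoothed$values - modes$mode1_center) * scale
  out <- dosage_matrix(vals, smoothed$markers, state = "normalized")
  # per-class mode estimate on the normalized scale
  cls <- unique(smoothed$markers$class)
  out$norm_modes <- lapply(stats::setNames(cls, cls), function(cl) {
    sc <- norm_target(cl) / sep
    list(mode1_center = 0, mode2_center = norm_target(cl),
         mode1_p95 = (modes$mode1_p95 - modes$mode1_center) * sc,
         split = (modes$split - modes$mode1_center) * sc)
  })
  out
}

#' Smooth-free normalization driver fitting modes per chromosome class
#'
#' Fits [fit_bimodal_modes()] separately on the pooled values of autosomal
#' and sex-chromosome markers (pooling clones, as the omnibus bimodal
#' histogram of a panel suggests) and normalizes each class to its own
#' target. Fitting per class makes the map idempotent: re-normalizing
#' already-normalized data is the identity.
#'
#' @param smoothed a smoothed `dosage_matrix`.
#' @param ... passed to [fit_bimodal_modes()].
#' @return a normalized `dosage_matrix` with per-class `norm_modes`.
#' @export
normalize_panel <- function(smoothed, ...) {
  stopifnot(inherits(smoothed, "dosage_matrix"))
  out_vals <- smoothed$values
  norm_modes <- list()
  for (cl in unique(smoothed$markers$class)) {
    idx <- which(smoothed$markers$class == cl)
    modes <- fit_bimodal_modes(as.vector(smoothed$values[idx, ]), ...)
    sep <- modes$mode2_center - modes$mode1_center
    sc <- norm_target(cl) / sep
    out_vals[idx, ] <- (smoothed$values[idx, ] - modes$mode1_center) * sc
    norm_modes[[cl]] <- list(mode1_center = 0, mode2_center = norm_target(cl),
                             mode1_p95 = (modes$mode1_p95 - modes$mode1_center) * sc,
                             split = (modes$split - modes$mode1_center) * sc,
                             raw_fit = modes)
  }
  out <- dosage_matrix(out_vals, smoothed$markers, state = "normalized")
  out$norm_modes <- norm_modes
  out
}

#' Call locus retention from normalized dosage
#'
#' For each locus and clone, the normalized log-ratio is averaged over the
#' `k` markers closest to the locus on its chromosome; the locus is called
#' retained when that mean exceeds the 95th percentile of the first
#' (no-gain) mode.
#'
#' @param normalized a normalized `dosage_matrix` (from [normalize_panel()]
#'   or [normalize_dosage()], which attach the threshold).
#' @param loci data.frame with columns `id`, `chrom`, `pos`.
#' @param k number of nearest markers to average.
#' @param threshold override for the retention threshold (normalized scale);
#'   default is the per-class first-mode 95th percentile.
#' @return an object of class `retention_table`: fields `calls` (locus x
#'   clone 0/1), `loci`, `per_locus_frequency`, `per_clone_fraction`.
#' @export
call_retention <- function(normalized, loci, k = 10, threshold = NULL) {
  stopifnot(inherits(normalized, "dosage_matrix"),
            normalized$state == "normalized",
            is.data.frame(loci), all(c("id", "chrom", "pos") %in% names(loci)))
  if (is.null(threshold) && is.null(normalized$norm_modes))
    stop("no mode estimate attached to the dosage matrix; supply `threshold`")
  m <- normalized$markers
  calls <- matrix(0L, nrow(loci), ncol(normalized$values),
                  dimnames = list(loci$id, colnames(normalized$values)))
  for (i in seq_len(nrow(loci))) {
    idx <- which(m$chrom == loci$chrom[i])
    if (length(idx) == 0L)
      stop("locus ", loci$id[i], " lies on a chromosome with no markers")
    nearest <- idx[order(abs(m$pos[idx] - loci$pos[i]))][seq_len(min(k, length(idx)))]
    avg <- colMeans(normalized$values[nearest, , drop = FALSE])
    thr <- if (!is.null(threshold)) threshold else
      normalized$norm_modes[[m$class[idx[1L]]]]$mode1_p95
    calls[i, ] <- as.integer(avg > thr)
  }
  structure(list(calls = calls, loci = loci,
                 per_locus_frequency = rowMeans(calls),
                 per_clone_fraction = colMeans(calls)),
            class = "retention_table")
}

#' @export
print.retention_table <- function(x, ...) {
  cat("retention_table:", nrow(x$calls), "loci x", ncol(x$calls),
      "clones; mean retention", round(mean(x$calls), 3), "\n")
  invisible(x)
}

#' Panel retention summaries
#'
#' @param table a `retention_table` (or a 0/1 locus x clone matrix).
#' @return list with `per_locus_frequency`, `per_clone_fraction`,
#'   `genome_mean` (grand mean retention) and `representation` =
#'   genome mean x clone count, the expected number of clones covering a
#'   random locus.
#' @export
retention_stats <- function(table) {
  calls <- if (inherits(table, "retention_table")) table$calls else as.matrix(table)
  if (length(calls) == 0L) stop("empty retention table")
  gm <- mean(calls)
  list(per_locus_frequency = rowMeans(calls),
       per_clone_fraction = colMeans(calls),
       genome_mean = gm,
       representation = gm * ncol(calls))
}

#' Concordance between aCGH retention calls and legacy genotypes
#'
#' Cross-tabulates the aCGH calls against a historical (e.g. PCR) 0/1
#' genotype table over the same loci and clones and reports the Pearson
#' chi-square (1 df, no continuity correction), plus the marker loss
#' fraction (legacy present, call absent) and gain fraction (legacy absent,
#' call present).
#'
#' @param table a `retention_table`.
#' @param legacy 0/1 matrix with matching locus rownames and clone colnames.
#' @return list with `table` (2x2), `statistic`, `df`, `p.value`,
#'   `loss_fraction`, `gain_fraction`.
#' @export
concordance_with_legacy <- function(table, legacy) {
  stopifnot(inherits(table, "retention_table"))
  legacy <- as.matrix(legacy)
  calls <- table$calls
  miss_l <- setdiff(rownames(calls), rownames(legacy))
  miss_c <- setdiff(rownames(legacy), rownames(calls))
  if (length(miss_l) || length(miss_c))
    stop("locus sets differ; only in calls: ",
         paste(miss_l, collapse = ","), "; only in legacy: ",
         paste(miss_c, collapse = ","))
  if (!setequal(colnames(calls), colnames(legacy)))
    stop("clone sets differ between calls and legacy table")
  legacy <- legacy[rownames(calls), colnames(calls), drop = FALSE]
  tab <- matrix(c(sum(calls == 0 & legacy == 0), sum(calls == 1 & legacy == 0),
                  sum(calls == 0 & legacy == 1), sum(calls == 1 & legacy == 1)),
                2L, 2L, dimnames = list(call = c("0", "1"), legacy = c("0", "1")))
  cs <- chisq_2x2(tab)
  list(table = tab, statistic = cs$statistic, df = cs$df, p.value = cs$p.value,
       loss_fraction = sum(legacy == 1 & calls == 0) / max(sum(legacy == 1), 1L),
       gain_fraction = sum(legacy == 0 & calls == 1) / max(sum(legacy == 0), 1L))
}

#' Test for preferential retention of centromeric regions
#'
#' Welch's two-sample t-test comparing per-locus retention frequencies for
#' loci inside vs outside annotated centromere intervals.
#'
#' @param table a `retention_table` whose loci carry `chrom`/`pos`.
#' @param genome an `rh_genome` with centromere annotation.
#' @param alternative test direction; `"greater"` tests for preferential
#'   centromeric retention.
#' @return list with `statistic`, `df`, `p.value`, group means and sizes.
#' @export
centromere_retention_test <- function(table, genome,
                                      alternative = c("two.sided", "greater",
                                                      "less")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(table, "retention_table"), inherits(genome, "rh_genome"))
  if (is.null(genome$centromeres)) stop("genome has no centromere annotation")
  loci <- table$loci
  cen <- genome$centromeres
  inside <- rep(FALSE, nrow(loci))
  for (j in seq_len(nrow(cen))) {
    inside <- inside | (loci$chrom == cen$chrom[j] &
                          loci$pos >= cen$start[j] & loci$pos < cen$end[j])
  }
  freq <- table$per_locus_frequency
  res <- welch_t(freq[inside], freq[!inside], alternative = alternative)
  c(res, list(n_centromeric = sum(inside), n_other = sum(!inside)))
}

# Recursive binary segmentation of one marker series: returns per-marker
# segment means. Splits are accepted while they improve a Gaussian BIC.
segment_series <- function(x, min_rss = 1e-12) {
  n <- length(x)
  seg_means <- rep(mean(x), n)
  recurse <- function(lo, hi) {
    m <- hi - lo + 1L
    if (m < 2L) return()
    v <- x[lo:hi]
    cs <- cumsum(v); css <- cumsum(v^2)
    tot_rss <- css[m] - cs[m]^2 / m
    k <- seq_len(m - 1L)
    rss_left <- css[k] - cs[k]^2 / k
    rss_right <- (css[m] - css[k]) - (cs[m] - cs[k])^2 / (m - k)
    rss_split <- rss_left + rss_right
    j <- which.min(rss_split)
    # Gaussian BIC: accept the split if the likelihood gain beats the
    # 2-parameter penalty (new mean + changepoint position)
    delta <- m * (log(max(rss_split[j], min_rss) / m) -
                    log(max(tot_rss, min_rss) / m)) + 2 * log(m)
    if (delta < 0) {
      seg_means[(lo + j - 1L + 1L):hi] <<- mean(x[(lo + j):hi])
      seg_means[lo:(lo + j - 1L)] <<- mean(x[lo:(lo + j - 1L)])
      recurse(lo, lo + j - 1L)
      recurse(lo + j, hi)
    }
  }
  recurse(1L, n)
  seg_means
}

#' Bin normalized dosage into 0/1 extra copies by segmentation
#'
#' Per clone and chromosome, the marker series is segmented by recursive
#' binary segmentation (within-segment variance minimization with a BIC
#' stopping rule) and each segment is assigned 0 or 1 extra copies by
#' whichever of 0 and the class-specific mode-2 target its mean is closer
#' to.
#'
#' @param normalized a normalized `dosage_matrix`.
#' @return a `dosage_matrix` with state `"binned"` and 0/1 values.
#' @export
bin_copy_number <- function(normalized) {
  stopifnot(inherits(normalized, "dosage_matrix"),
            normalized$state == "normalized")
  m <- normalized$markers
  out <- normalized$values
  for (ch in unique(m$chrom)) {
    idx <- which(m$chrom == ch)
    target <- norm_target(m$class[idx[1L]])
    for (cl in seq_len(ncol(out))) {
      mu <- segment_series(normalized$values[idx, cl])
      out[idx, cl] <- as.numeric(abs(mu - target) < abs(mu))
    }
  }
  dosage_matrix(out, m, state = "binned")
}
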