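# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed
#'
#' Each pipeline stage consumes its own child seed so that regenerating a
#' single stage is possible without replaying the whole stream. The map is a
#' fixed affine hash modulo 2^31 - 1, so child seeds stay valid R integers.
#'
#' @param seed master seed (integer).
#' @param stage integer offset identifying the stage (>= 0).
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) * 48271 + stage * 16807 + 1) %% 2147483647)
}

# Pearson chi-square on a 2x2 table, no continuity correction by default.
# Returns the statistic, df = 1 and the upper-tail P.
chisq_2x2 <- function(tab, correct = FALSE) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  n <- sum(tab)
  if (n == 0) stop("empty contingency table")
  expected <- outer(rowSums(tab), colSums(tab)) / n
  if (any(expected == 0)) stop("degenerate margin in 2x2 table")
  dev <- abs(tab - expected)
  if (correct) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  list(statistic = stat, df = 1L, p.value = stats::pchisq(stat, 1L, lower.tail = FALSE),
       expected = expected, observed = tab)
}

# Welch's two-sample t-test from raw samples; explicit formulas so tests can
# cross-check against stats::t.test.
welch_t <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) stop("need >= 2 finite values per group")
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1L) + vy^2 / (length(y) - 1L))
  p <- switch(alternative,
    two.sided = 2 * stats::pt(abs(t), df, lower.tail = FALSE),
    greater   = stats::pt(t, df, lower.tail = FALSE),
    less      = stats::pt(t, df))
  list(statistic = t, df = df, p.value = p,
       mean_x = mean(x), mean_y = mean(y), alternative = alternative)
}

# Distance in bp from a point to an interval [start, end) ; 0 if inside.
point_interval_distance <- function(pos, start, end) {
  d <- pmax(start - pos, pos - (end - 1L), 0)
  d[pos >= start & pos < end] <- 0
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a
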