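# aCGH processing: smoothing, mode fitting, normalization, retention calls,
# concordance and copy-number binning.

mini_dosage <- function(values, chrom = "c1", class = "autosome",
                        state = "raw") {
  values <- as.matrix(values)
  dosage_matrix(values,
                data.frame(id = sprintf("m%03d", seq_len(nrow(values))),
                           chrom = chrom, pos = seq_len(nrow(values)) * 1e5,
                           class = class, stringsAsFactors = FALSE),
                state = state)
}

test_that("sliding-window smoothing matches a hand rolling-mean oracle", {
  # constant input and window 1 are identities
  const <- mini_dosage(matrix(0.3, 20, 2))
  expect_equal(sliding_window_smooth(const, 10)$values, const$values,
               ignore_attr = TRUE)
  x <- mini_dosage(matrix(rnorm(30), 15, 2))
  expect_equal(sliding_window_smooth(x, 1)$values, x$values,
               ignore_attr = TRUE)
  # spike with window 3 (centered, truncated at the ends)
  spike <- mini_dosage(matrix(c(0, 0, 1, 0, 0, 0), ncol = 1))
  sm <- sliding_window_smooth(spike, 3)
  expect_equal(as.vector(sm$values), c(0, 1/3, 1/3, 1/3, 0, 0))
  # windows never cross chromosomes
  two <- dosage_matrix(
    matrix(c(1, 1, 1, 0, 0, 0), ncol = 1),
    data.frame(id = sprintf("m%d", 1:6), chrom = rep(c("c1", "c2"), each = 3),
               pos = rep(c(1e5, 2e5, 3e5), 2), class = "autosome"))
  expect_equal(as.vector(sliding_window_smooth(two, 3)$values),
               c(1, 1, 1, 0, 0, 0))
})

test_that("oversized window falls back to the chromosome mean with a warning", {
  x <- mini_dosage(matrix(1:5 / 10, 5, 1))
  expect_warning(sm <- sliding_window_smooth(x, 10), "whole-chromosome mean")
  expect_equal(as.vector(sm$values), rep(0.3, 5))
})

test_that("smoothing approximately preserves the per-chromosome mean", {
  set.seed(5)
  x <- mini_dosage(matrix(rnorm(200), 100, 2))
  sm <- sliding_window_smooth(x, 10)
  # edge truncation re-weights only the outer few markers
  expect_lt(max(abs(colMeans(sm$values) - colMeans(x$values))), 0.05)
})

test_that("fit_bimodal_modes locates degenerate and Gaussian modes", {
  # equal point masses: exact centers and p95
  v <- rep(c(0, 0.176), each = 500)
  m <- fit_bimodal_modes(v)
  expect_equal(m$mode1_center, 0, tolerance = 1e-6)
  expect_equal(m$mode2_center, 0.176, tolerance = 1e-6)
  expect_equal(unname(m$mode1_p95), 0)
  # two-Gaussian sample: centers within 0.01 of component means
  set.seed(8)
  v2 <- c(rnorm(5000, 0.05, 0.02), rnorm(5000, 0.25, 0.02))
  m2 <- fit_bimodal_modes(v2)
  expect_lt(abs(m2$mode1_center - 0.05), 0.01)
  expect_lt(abs(m2$mode2_center - 0.25), 0.01)
  expect_true(m2$mode1_p95 > m2$mode1_center && m2$mode1_p95 < m2$mode2_center)
  # degenerate inputs
  expect_error(fit_bimodal_modes(rep(0.1, 200)), "no gain detected")
  set.seed(9)
  expect_error(fit_bimodal_modes(rnorm(2000, 0, 0.02)), "no gain detected")
})

test_that("normalize_dosage applies the class-specific affine map", {
  modes <- structure(list(mode1_center = 0.05, mode2_center = 0.25,
                          mode1_p95 = 0.08, split = 0.15),
                     class = "mode_estimate")
  auto <- mini_dosage(matrix(c(0.05, 0.25), 2, 1), state = "smoothed")
  na <- normalize_dosage(auto, modes)
  expect_equal(as.vector(na$values), c(0, log10(3/2)), tolerance = 1e-12)
  sexm <- mini_dosage(matrix(c(0.05, 0.25), 2, 1), class = "sex",
                      state = "smoothed")
  ns <- normalize_dosage(sexm, modes)
  expect_equal(as.vector(ns$values), c(0, log10(2)), tolerance = 1e-12)
  # already-normalized autosomal modes: identity
  id_modes <- structure(list(mode1_center = 0, mode2_center = log10(3/2),
                             mode1_p95 = 0.01, split = 0.08),
                        class = "mode_estimate")
  again <- normalize_dosage(na, id_modes)
  expect_equal(again$values, na$values, tolerance = 1e-12)
  # degenerate separation
  bad <- modes; bad$mode2_center <- bad$mode1_center + 1e-9
  expect_error(normalize_dosage(auto, bad), "degenerate mode separation")
})

test_that("normalize_panel is idempotent and centers both classes", {
  g <- small_genome()
  cfg <- sim_config(n_clones = 30, seed = 12)
  truth <- simulate_fragments(g, cfg)
  raw <- simulate_acgh(truth, g, cfg)
  sm <- sliding_window_smooth(raw, 10)
  norm1 <- normalize_panel(sm)
  norm2 <- normalize_panel(norm1)
  expect_lt(max(abs(norm2$values - norm1$values)), 1e-6)
  for (cl in c("autosome", "sex")) {
    refit <- fit_bimodal_modes(as.vector(norm1$values[norm1$markers$class == cl, ]))
    target <- if (cl == "sex") log10(2) else log10(3 / 2)
    expect_lt(abs(refit$mode1_center), 0.005)
    expect_lt(abs(refit$mode2_center - target), 0.005)
  }
})

test_that("retention calls follow the k-nearest-mean rule", {
  g <- small_genome()
  cfg <- sim_config(n_clones = 12, acgh_noise_sd = 0, seed = 21)
  truth <- simulate_fragments(g, cfg)
  norm <- normalize_panel(sliding_window_smooth(simulate_acgh(truth, g, cfg), 1))
  loci <- data.frame(id = c("sel", "far"),
                     chrom = c(g$selectable_locus$chrom, "chrX"),
                     pos = c(g$selectable_locus$pos, 1.5e7))
  rt <- call_retention(norm, loci, k = 10)
  expect_true(all(rt$calls["sel", ] == 1L))
  # a clone with no extra copies anywhere is never called retained
  set.seed(1)
  d0 <- mini_dosage(matrix(rnorm(40 * 12, 0, 0.01), 40, 12), state = "raw")
  d0$state <- "normalized"
  rt0 <- call_retention(d0, data.frame(id = "L0", chrom = "c1", pos = 2e6),
                        k = 10, threshold = 0.05)
  expect_true(all(rt0$calls == 0L))
  # hand-computed mixed case: 6 of 10 nearest markers gained, no noise
  vals <- matrix(0, 20, 1)
  vals[6:11, 1] <- log10(3/2)
  d <- mini_dosage(vals, state = "raw")
  d$state <- "normalized"
  mixed <- call_retention(d, data.frame(id = "L", chrom = "c1", pos = 8.5e5),
                          k = 10, threshold = 0)
  expect_identical(unname(mixed$calls[1, 1]), 1L)  # mean 6/10*0.176 > 0
  expect_error(call_retention(d, data.frame(id = "L2", chrom = "nochrom",
                                            pos = 1), k = 10, threshold = 0),
               "L2")
})

test_that("retention calls are invariant under affine transforms of raw data", {
  g <- small_genome()
  cfg <- sim_config(n_clones = 15, seed = 33)
  truth <- simulate_fragments(g, cfg)
  raw <- simulate_acgh(truth, g, cfg)
  loci <- data.frame(id = sprintf("L%d", 1:5), chrom = "chr1",
                     pos = seq(2e6, 2.6e7, length.out = 5))
  call1 <- call_retention(normalize_panel(sliding_window_smooth(raw, 10)), loci)
  raw2 <- raw
  raw2$values <- 2.0 * raw$values + 0.3
  call2 <- call_retention(normalize_panel(sliding_window_smooth(raw2, 10)), loci)
  expect_identical(call1$calls, call2$calls)
})

test_that("retention_stats reports frequency and genome representation", {
  all_ret <- matrix(1L, 4, 10)
  s <- retention_stats(all_ret)
  expect_equal(s$genome_mean, 1)
  expect_equal(s$representation, 10)
  # the panel bookkeeping: frequency 0.11 over 79 clones represents the
  # genome about 9 times
  freq11 <- matrix(0L, 100, 79)
  freq11[, 1:79] <- replicate(79, as.integer(seq_len(100) <= 11))
  s2 <- retention_stats(freq11)
  expect_equal(s2$representation, 0.11 * 79)
  expect_equal(round(s2$representation), 9)
  expect_error(retention_stats(matrix(0L, 0, 0)), "empty")
})

test_that("legacy concordance reproduces the textbook chi-square", {
  calls <- matrix(c(1L, 0L, 1L, 1L, 0L, 0L, 1L, 0L), 4, 2,
                  dimnames = list(paste0("L", 1:4), c("a", "b")))
  rt <- structure(list(calls = calls,
                       loci = data.frame(id = paste0("L", 1:4), chrom = "c1",
                                         pos = 1:4),
                       per_locus_frequency = rowMeans(calls),
                       per_clone_fraction = colMeans(calls)),
                  class = "retention_table")
  set.seed(4)
  legacy <- matrix(rbinom(8, 1, 0.5), 4, 2,
                   dimnames = dimnames(calls))
  res <- concordance_with_legacy(rt, legacy)
  oracle <- suppressWarnings(stats::chisq.test(res$table, correct = FALSE))
  expect_equal(res$statistic, unname(oracle$statistic))
  expect_equal(res$p.value, oracle$p.value)
  # identical tables: no loss, no gain
  res2 <- concordance_with_legacy(rt, calls)
  expect_equal(res2$loss_fraction, 0)
  expect_equal(res2$gain_fraction, 0)
  # mismatched loci are reported by name
  bad <- legacy; rownames(bad) <- c("L1", "L2", "L3", "L9")
  expect_error(concordance_with_legacy(rt, bad), "L4|L9")
})

test_that("legacy concordance P is near-uniform under independence", {
  set.seed(17)
  ps <- replicate(200, {
    calls <- matrix(rbinom(400, 1, 0.5), 20, 20,
                    dimnames = list(paste0("L", 1:20), paste0("c", 1:20)))
    rt <- structure(list(calls = calls,
                         loci = data.frame(id = rownames(calls), chrom = "c1",
                                           pos = 1:20),
                         per_locus_frequency = rowMeans(calls),
                         per_clone_fraction = colMeans(calls)),
                    class = "retention_table")
    legacy <- matrix(rbinom(400, 1, 0.5), 20, 20, dimnames = dimnames(calls))
    concordance_with_legacy(rt, legacy)$p.value
  })
  expect_gt(mean(ps), 0.40)
  expect_lt(mean(ps), 0.60)
})

test_that("centromere retention test matches the Welch formula", {
  g <- small_genome()
  # closed-form oracle on hand samples via stats::t.test
  x <- c(0.9, 0.85, 0.95, 0.8, 0.92)
  y <- c(0.1, 0.12, 0.09, 0.15, 0.2, 0.11)
  ours <- rhceqtl:::welch_t(x, y)
  oracle <- stats::t.test(x, y)
  expect_equal(ours$statistic, unname(oracle$statistic))
  expect_equal(ours$df, unname(oracle$parameter))
  expect_equal(ours$p.value, oracle$p.value)
  # planted centromere bias is detected
  cfg <- sim_config(n_clones = 60, centromere_retention_multiplier = 4,
                    seed = 19)
  truth <- simulate_fragments(g, cfg)
  rt <- structure(list(calls = truth$copy_state,
                       loci = data.frame(id = g$markers$id,
                                         chrom = g$markers$chrom,
                                         pos = g$markers$pos),
                       per_locus_frequency = rowMeans(truth$copy_state),
                       per_clone_fraction = colMeans(truth$copy_state)),
                  class = "retention_table")
  res <- centromere_retention_test(rt, g, alternative = "greater")
  expect_lt(res$p.value, 0.05)
  g_nocen <- g; g_nocen$centromeres <- NULL
  expect_error(centromere_retention_test(rt, g_nocen), "centromere")
})

test_that("copy-number binning recovers block structure", {
  # noiseless alternating blocks: exact recovery
  tgt <- log10(3/2)
  blocks <- rep(c(0, 1, 0, 1, 0), times = c(30, 20, 25, 15, 30))
  d <- mini_dosage(matrix(blocks * tgt, ncol = 1), state = "raw")
  d$state <- "normalized"
  b <- bin_copy_number(d)
  expect_identical(as.vector(b$values), blocks)
  # noisy series: >= 99% agreement
  set.seed(23)
  dn <- mini_dosage(matrix(blocks * tgt + rnorm(length(blocks), 0, 0.03),
                           ncol = 1), state = "raw")
  dn$state <- "normalized"
  bn <- bin_copy_number(dn)
  expect_gte(mean(bn$values == blocks), 0.99)
})

test_that("alpha from binned and continuous dosage agree on a panel", {
  fx <- default_panel()
  g <- fx$genome; panel <- fx$panel
  binned <- bin_copy_number(panel$normalized)
  nm <- nearest_marker(g)
  a_cont <- vapply(seq_len(nrow(g$genes)), function(i)
    fit_dosage_model(panel$expression$values[i, ],
                     panel$normalized$values[nm[g$genes$id[i]], ])$alpha,
    numeric(1))
  a_bin <- vapply(seq_len(nrow(g$genes)), function(i) {
    x <- binned$values[nm[g$genes$id[i]], ]
    if (stats::sd(x) == 0) return(NA_real_)
    fit_dosage_model(panel$expression$values[i, ], x)$alpha
  }, numeric(1))
  ok <- is.finite(a_bin)
  expect_gte(stats::cor(a_cont[ok], a_bin[ok]), 0.9)
})
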