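#' Simulation configuration for a synthetic radiation hybrid panel
#'
#' Defaults encode the panel summaries the analysis is calibrated against:
#' a per-marker donor retention frequency of 11.4%, a mean donor fragment
#' length of 4 Mb, a bimodal cis effect-size distribution with component
#' means 0.73 (positive) and -0.12 (negative), 36% negative effects, and a
#' 0.5 attenuation multiplier on X-linked effect sizes.
#'
#' @param n_clones number of hybrid clones (79 in a classic human panel).
#' @param target_retention expected fraction of donor markers retained per
#'   clone; must lie strictly in (0, 1).
#' @param mean_fragment_length mean donor fragment length in bp
#'   (exponential lengths).
#' @param centromere_retention_multiplier fragment start-point intensity
#'   multiplier inside centromere intervals; 1 disables the bias.
#' @param acgh_noise_sd Gaussian noise sd on raw aCGH log10 ratios.
#' @param expr_noise_sd Gaussian noise sd on expression log10 ratios.
#' @param alpha_positive_mean,alpha_negative_mean means of the positive and
#'   negative effect-size components (slopes of expression log-ratio on
#'   dosage log-ratio).
#' @param alpha_positive_sd,alpha_negative_sd component sds.
#' @param fraction_negative fraction of genes with negative cis effect.
#' @param x_attenuation_factor multiplier in (0, 1] applied to |alpha| of
#'   genes on sex chromosomes (dosage-compensation-like attenuation).
#' @param n_trans_links number of planted trans regulatory links.
#' @param trans_alpha_mean,trans_alpha_sd effect size distribution of trans
#'   links (trans effects in RH panels are almost all positive).
#' @param raw_mode_separation log10 distance between the two raw aCGH
#'   modes before normalization; log10(3/2) mimics a single extra copy on a
#'   diploid background.
#' @param raw_offset position of the lower raw mode (nonzero so that
#'   normalization is nontrivial).
#' @param clone_retention_sd optional lognormal sd of a per-clone retention
#'   multiplier; 0 keeps all clones at the common target.
#' @param seed master seed; each stage derives a documented child seed.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_clones = 79,
                       target_retention = 0.114,
                       mean_fragment_length = 4e6,
                       centromere_retention_multiplier = 1,
                       acgh_noise_sd = 0.03,
                       expr_noise_sd = 0.05,
                       alpha_positive_mean = 0.73,
                       alpha_negative_mean = -0.12,
                       alpha_positive_sd = 0.25,
                       alpha_negative_sd = 0.08,
                       fraction_negative = 0.36,
                       x_attenuation_factor = 0.5,
                       n_trans_links = 0,
                       trans_alpha_mean = 1.0,
                       trans_alpha_sd = 0.3,
                       raw_mode_separation = log10(3 / 2),
                       raw_offset = 0.05,
                       clone_retention_sd = 0,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_clones < 1) stop("invalid n_clones: need at least one clone")
  if (!(cfg$target_retention > 0 && cfg$target_retention < 1))
    stop("invalid target_retention: must be strictly between 0 and 1")
  if (cfg$mean_fragment_length <= 0) stop("invalid mean_fragment_length")
  if (cfg$centromere_retention_multiplier < 1)
    stop("invalid centromere_retention_multiplier: must be >= 1")
  if (cfg$acgh_noise_sd < 0 || cfg$expr_noise_sd < 0)
    stop("noise sds must be >= 0")
  if (!(cfg$fraction_negative >= 0 && cfg$fraction_negative <= 1))
    stop("invalid fraction_negative")
  if (!(cfg$x_attenuation_factor > 0 && cfg$x_attenuation_factor <= 1))
    stop("invalid x_attenuation_factor: must be in (0, 1]")
  if (cfg$raw_mode_separation <= 0) stop("invalid raw_mode_separation")
  if (cfg$n_trans_links < 0) stop("invalid n_trans_links")
  structure(cfg, class = "sim_config")
}

# Merge possibly overlapping fragment intervals on one chromosome into a
# disjoint sorted set.
merge_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) me <- max(me, end[i]) else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

#' Simulate donor fragment retention for each clone
#'
#' Fragment start points follow a homogeneous Poisson process along each
#' chromosome with exponential fragment lengths (mean L), truncated at
#' chromosome ends; the stationary coverage probability of such a process
#' is `1 - exp(-lambda * L)`. One additional fragment per clone is forced
#' to cover the selectable-marker locus *and* the aCGH marker nearest to
#' it, reproducing the 100% retention observed at the locus under
#' selection; by memorylessness the forced fragment's overhangs on either
#' side are themselves exponential with mean L (the length-biased
#' distribution of a point-covering fragment). The base rate `lambda` is
#' tuned down to compensate for the forced fragment so the marker-averaged
#' retention still matches `target_retention`. When the centromere
#' multiplier exceeds 1, extra start points are laid down inside centromere
#' intervals.
#'
#' @param genome an `rh_genome`.
#' @param config a `sim_config`.
#' @param seed seed; defaults to a child of `config$seed`.
#' @return an object of class `panel_truth` with elements `fragments` (list
#'   per clone of data.frames chrom/start/end/forced), `copy_state` (marker
#'   x clone 0/1 matrix) and `clone_ids`.
#' @export
simulate_fragments <- function(genome, config, seed = NULL) {
  stopifnot(inherits(genome, "rh_genome"), inherits(config, "sim_config"))
  if (nrow(genome$markers) == 0L) stop("invalid genome: zero markers")
  set.seed(seed %||% derive_seed(config$seed, 1L))

  L <- config$mean_fragment_length
  chroms <- genome$chromosomes
  sel <- genome$selectable_locus
  n_clones <- config$n_clones

  # nearest marker to the selectable locus (guaranteed retained)
  sel_midx <- which(genome$markers$chrom == sel$chrom)
  if (length(sel_midx) == 0L)
    stop("no markers on the selectable-marker chromosome")
  sel_mpos <- genome$markers$pos[sel_midx[
    which.min(abs(genome$markers$pos[sel_midx] - sel$pos))]]
  span <- abs(sel_mpos - sel$pos) + 1
  G <- sum(chroms$length)
  # expected marker-averaged coverage contributed by the forced fragment
  q_bar <- min((span + 2 * L) / G, 0.999)
  p0 <- 1 - (1 - config$target_retention) / (1 - q_bar)
  if (p0 <= 0)
    stop("invalid target_retention/mean_fragment_length: forced ",
         "selectable-locus fragment alone exceeds the retention target ",
         "on this genome")
  lambda <- -log(1 - p0) / L  # per-bp start rate of the base process
  clone_mult <- if (config$clone_retention_sd > 0)
    stats::rlnorm(n_clones, -config$clone_retention_sd^2 / 2,
                  config$clone_retention_sd) else rep(1, n_clones)

  fragments <- vector("list", n_clones)
  copy_state <- matrix(0L, nrow(genome$markers), n_clones,
                       dimnames = list(genome$markers$id, NULL))
  for (cl in seq_len(n_clones)) {
    frags <- list()
    for (i in seq_len(nrow(chroms))) {
      clen <- chroms$length[i]
      n_base <- stats::rpois(1L, lambda * clone_mult[cl] * clen)
      starts <- stats::runif(n_base, 0, clen)
      if (!is.null(genome$centromeres) &&
          config$centromere_retention_multiplier > 1) {
        cen <- genome$centromeres[genome$centromeres$chrom == chroms$name[i], ]
        if (nrow(cen) > 0) {
          extra_rate <- lambda * clone_mult[cl] *
            (config$centromere_retention_multiplier - 1)
          for (j in seq_len(nrow(cen))) {
            n_extra <- stats::rpois(1L, extra_rate * (cen$end[j] - cen$start[j]))
            starts <- c(starts, stats::runif(n_extra, cen$start[j], cen$end[j]))
          }
        }
      }
      if (length(starts) == 0L) next
      lens <- stats::rexp(length(starts), 1 / L)
      frags[[chroms$name[i]]] <- data.frame(
        chrom = chroms$name[i], start = starts,
        end = pmin(starts + lens, clen), forced = FALSE,
        stringsAsFactors = FALSE)
    }
    # forced fragment covering the selectable locus and its nearest marker;
    # exponential overhangs on both sides (length-biased point coverage)
    sel_clen <- chroms$length[chroms$name == sel$chrom]
    lo <- min(sel$pos, sel_mpos)
    hi <- max(sel$pos, sel_mpos) + 1
    sel_start <- max(0, lo - stats::rexp(1L, 1 / L))
    sel_end <- min(sel_clen, max(hi, hi + stats::rexp(1L, 1 / L)))
    frags[[length(frags) + 1L]] <- data.frame(
      chrom = sel$chrom, start = sel_start, end = sel_end, forced = TRUE,
      stringsAsFactors = FALSE)
    fr <- do.call(rbind, frags)
    rownames(fr) <- NULL
    fragments[[cl]] <- fr

    for (ch in unique(fr$chrom)) {
      iv <- merge_intervals(fr$start[fr$chrom == ch], fr$end[fr$chrom == ch])
      midx <- which(genome$markers$chrom == ch)
      if (length(midx) == 0L) next
      pos <- genome$markers$pos[midx]
      # covered iff pos falls in [start, end) of a merged interval
      k <- findInterval(pos, as.vector(t(iv)))
      copy_state[midx[k %% 2L == 1L], cl] <- 1L
    }
  }
  structure(list(fragments = fragments, copy_state = copy_state,
                 clone_ids = sprintf("clone%02d", seq_len(n_clones)),
                 genome = genome, config = config),
            class = "panel_truth")
}

#' @export
print.panel_truth <- function(x, ...) {
  cat("panel_truth:", length(x$fragments), "clones, retention",
      round(mean(x$copy_state), 3), "\n")
  invisible(x)
}

#' Simulate raw aCGH log-ratio data from planted copy states
#'
#' Raw value = offset + copy_state x mode separation + Gaussian noise, i.e.
#' a bimodal log10 ratio distribution whose lower mode sits at a nonzero
#' offset (so normalization has real work to do).
#'
#' @param truth a `panel_truth` from [simulate_fragments()].
#' @param genome the `rh_genome` used to build `truth`.
#' @param config a `sim_config`.
#' @param seed seed; defaults to a child of `config$seed`.
#' @return a raw `dosage_matrix`.
#' @export
simulate_acgh <- function(truth, genome, config, seed = NULL) {
  stopifnot(inherits(truth, "panel_truth"), inherits(config, "sim_config"))
  set.seed(seed %||% derive_seed(config$seed, 2L))
  cs <- truth$copy_state
  vals <- config$raw_offset + cs * config$raw_mode_separation
  if (config$acgh_noise_sd > 0)
    vals <- vals + stats::rnorm(length(vals), 0, config$acgh_noise_sd)
  colnames(vals) <- truth$clone_ids
  dosage_matrix(vals, genome$markers, state = "raw")
}

#' Plant per-gene effect sizes and trans links
#'
#' Cis effect sizes are drawn from a two-component Gaussian mixture: with
#' probability `fraction_negative` from the negative component (truncated at
#' 0 from above), otherwise from the positive component (truncated at 0 from
#' below). Genes on sex chromosomes have |alpha| multiplied by
#' `x_attenuation_factor`. Trans links pair a random source marker with a
#' random gene on another chromosome.
#'
#' @inheritParams simulate_acgh
#' @return `truth` augmented with `gene_alpha` (data.frame id/mu/alpha),
#'   `trans_links` (data.frame marker/gene/alpha) and `nearest_marker`.
#' @export
plant_effects <- function(truth, genome, config, seed = NULL) {
  stopifnot(inherits(truth, "panel_truth"), inherits(config, "sim_config"))
  set.seed(seed %||% derive_seed(config$seed, 3L))
  g <- genome$genes
  n <- nrow(g)
  neg <- stats::runif(n) < config$fraction_negative
  rtrunc <- function(n, mean, sd, lower) {
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- if (lower) x <= 0 else x >= 0))
      x[bad] <- stats::rnorm(sum(bad), mean, sd)
    x
  }
  alpha <- numeric(n)
  if (any(!neg))
    alpha[!neg] <- rtrunc(sum(!neg), config$alpha_positive_mean,
                          config$alpha_positive_sd, lower = TRUE)
  if (any(neg))
    alpha[neg] <- rtrunc(sum(neg), config$alpha_negative_mean,
                         config$alpha_negative_sd, lower = FALSE)
  cls <- genome$chromosomes$class[match(g$chrom, genome$chromosomes$name)]
  alpha[cls == "sex"] <- alpha[cls == "sex"] * config$x_attenuation_factor
  mu <- stats::rnorm(n, 0, 0.1)
  truth$gene_alpha <- data.frame(id = g$id, mu = mu, alpha = alpha,
                                 chrom_class = cls, stringsAsFactors = FALSE)
  truth$nearest_marker <- nearest_marker(genome)

  if (config$n_trans_links > 0) {
    src <- sample(genome$markers$id, config$n_trans_links, replace = TRUE)
    src_chrom <- genome$markers$chrom[match(src, genome$markers$id)]
    tgt <- vapply(src_chrom, function(ch)
      sample(g$id[g$chrom != ch], 1L), character(1))
    truth$trans_links <- data.frame(
      marker = src, gene = tgt,
      alpha = stats::rnorm(config$n_trans_links, config$trans_alpha_mean,
                           config$trans_alpha_sd),
      stringsAsFactors = FALSE)
  } else {
    truth$trans_links <- data.frame(marker = character(0), gene = character(0),
                                    alpha = numeric(0))
  }
  truth
}

#' Simulate expression log-ratios from normalized dosage
#'
#' y[gene, clone] = mu + alpha x dosage at the gene's nearest marker, plus
#' planted trans contributions at their source markers, plus Gaussian noise.
#' The dosage regressor is the *normalized* matrix, so with zero noise the
#' mapping stage recovers the planted effect sizes exactly.
#'
#' @param truth a `panel_truth` with effects planted (see [plant_effects()]).
#' @param normalized_dosage a normalized `dosage_matrix`.
#' @inheritParams simulate_acgh
#' @return an `expression_matrix`.
#' @export
simulate_expression <- function(truth, normalized_dosage, config, seed = NULL) {
  stopifnot(inherits(truth, "panel_truth"),
            inherits(normalized_dosage, "dosage_matrix"),
            inherits(config, "sim_config"))
  if (is.null(truth$gene_alpha))
    stop("truth has no planted effects; call plant_effects() first")
  set.seed(seed %||% derive_seed(config$seed, 4L))
  genome <- truth$genome
  g <- genome$genes
  dv <- normalized_dosage$values
  x_cis <- dv[truth$nearest_marker[g$id], , drop = FALSE]
  y <- truth$gene_alpha$mu + truth$gene_alpha$alpha * x_cis
  rownames(y) <- g$id
  if (nrow(truth$trans_links) > 0) {
    for (i in seq_len(nrow(truth$trans_links))) {
      tl <- truth$trans_links[i, ]
      y[tl$gene, ] <- y[tl$gene, ] + tl$alpha * dv[tl$marker, ]
    }
  }
  if (config$expr_noise_sd > 0)
    y <- y + stats::rnorm(length(y), 0, config$expr_noise_sd)
  colnames(y) <- colnames(dv)
  expression_matrix(y, g)
}

#' Run the full simulation: fragments, aCGH, normalization, expression
#'
#' Convenience wrapper chaining [simulate_fragments()], [simulate_acgh()],
#' [sliding_window_smooth()], [normalize_panel()], [plant_effects()] and
#' [simulate_expression()] with child seeds derived from `config$seed`.
#'
#' @inheritParams simulate_fragments
#' @param window sliding-window width for smoothing.
#' @return list with `truth`, `raw`, `normalized` (dosage matrices) and
#'   `expression`.
#' @export
simulate_panel <- function(genome, config, window = 10) {
  truth <- simulate_fragments(genome, config)
  raw <- simulate_acgh(truth, genome, config)
  sm <- sliding_window_smooth(raw, window = window)
  norm <- normalize_panel(sm)
  truth <- plant_effects(truth, genome, config)
  expr <- simulate_expression(truth, norm, config)
  list(truth = truth, raw = raw, normalized = norm, expression = expr)
}
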