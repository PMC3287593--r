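#' Poisson tail test for trans-regulation hotspots
#'
#' Counts regulated genes per marker (`direction = "per-marker"`) or
#' regulating markers per gene (`"per-gene"`) among trans records passing a
#' q-value threshold, models counts as Poisson with mean lambda equal to
#' the average count, and reports the upper tail P = Pr(X > count) with
#' Benjamini-Hochberg adjustment over units.
#'
#' @param trans_records data.frame of trans ceQTL records (columns `gene`,
#'   `marker`, `q`).
#' @param q_threshold keep records with `q <` this value.
#' @param direction count genes per marker or markers per gene.
#' @param include_zero_units if TRUE, lambda averages over every unit in
#'   `universe` (units with no trans hit count as zero); default averages
#'   over units with at least one hit.
#' @param universe optional character vector of all unit ids (required when
#'   `include_zero_units` is TRUE).
#' @return data.frame: unit, count, lambda, P, q.
#' @export
hotspot_fdr <- function(trans_records, q_threshold = 0.25,
                        direction = c("per-marker", "per-gene"),
                        include_zero_units = FALSE, universe = NULL) {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(trans_records))
  r <- trans_records[trans_records$q < q_threshold, , drop = FALSE]
  if (nrow(r) == 0L) stop("no trans records pass the q threshold")
  unit <- if (direction == "per-marker") r$marker else r$gene
  other <- if (direction == "per-marker") r$gene else r$marker
  counts <- tapply(other, unit, function(v) length(unique(v)))
  counts <- counts[order(names(counts))]
  if (include_zero_units) {
    if (is.null(universe)) stop("universe required when counting zero units")
    zero <- setdiff(universe, names(counts))
    counts <- c(counts, stats::setNames(rep(0L, length(zero)), zero))
  }
  lambda <- mean(counts)
  p <- stats::ppois(counts, lambda, lower.tail = FALSE)  # Pr(X > count)
  data.frame(unit = names(counts), count = as.integer(counts),
             lambda = lambda, P = as.numeric(p),
             q = stats::p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Distance from each peak position to the nearest annotated interval on its
# chromosome (Inf when the chromosome carries no annotation).
peak_annotation_distance <- function(peaks, annotation) {
  vapply(seq_len(nrow(peaks)), function(i) {
    a <- annotation[annotation$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(a) == 0L) return(Inf)
    min(point_interval_distance(peaks$pos[i], a$start, a$end))
  }, numeric(1))
}

#' Select peaks lying in noncoding territory
#'
#' A peak is noncoding when its distance to the nearest annotated gene or
#' microRNA interval on its chromosome exceeds `exclusion` (distance to an
#' interval is the gap to the nearer boundary, 0 inside).
#'
#' @param peaks data.frame with columns `chrom`, `pos` (and anything else,
#'   carried through).
#' @param annotation data.frame of gene + microRNA intervals: `chrom`,
#'   `start`, `end`.
#' @param exclusion minimum distance in bp (300 kb by convention: about
#'   twice the 2-unit -log10 P support radius of a peak).
#' @return the noncoding subset of `peaks` with a `gene_distance` column.
#' @export
define_noncoding <- function(peaks, annotation, exclusion = 3e5) {
  stopifnot(is.data.frame(peaks), all(c("chrom", "pos") %in% names(peaks)),
            is.data.frame(annotation),
            all(c("chrom", "start", "end") %in% names(annotation)))
  peaks$gene_distance <- peak_annotation_distance(peaks, annotation)
  peaks[peaks$gene_distance > exclusion, , drop = FALSE]
}

#' Merge nearby noncoding peaks into blocks
#'
#' Single-linkage chaining per chromosome: consecutive peaks at most
#' `merge_distance` apart join the same block; the block interval spans its
#' member positions. Output is independent of input order.
#'
#' @param peaks data.frame with columns `chrom`, `pos`; a `neg_log10_p`
#'   column, if present, yields the block's best score.
#' @param merge_distance chaining distance in bp.
#' @return data.frame of blocks: block id, chrom, start, end, n_peaks,
#'   best_neg_log10_p, with attribute `members` (list of member row
#'   indices of the sorted peak set).
#' @export
merge_blocks <- function(peaks, merge_distance = 3e5) {
  stopifnot(is.data.frame(peaks), all(c("chrom", "pos") %in% names(peaks)))
  if (nrow(peaks) == 0L)
    return(data.frame(block = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      n_peaks = integer(0), best_neg_log10_p = numeric(0)))
  peaks <- peaks[order(peaks$chrom, peaks$pos), , drop = FALSE]
  out <- list(); members <- list()
  for (ch in unique(peaks$chrom)) {
    p <- peaks[peaks$chrom == ch, , drop = FALSE]
    grp <- cumsum(c(1L, diff(p$pos) > merge_distance))
    for (g in unique(grp)) {
      sel <- p[grp == g, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        block = sprintf("%s_block%03d", ch, g), chrom = ch,
        start = min(sel$pos), end = max(sel$pos), n_peaks = nrow(sel),
        best_neg_log10_p = if ("neg_log10_p" %in% names(sel))
          max(sel$neg_log10_p) else NA_real_,
        stringsAsFactors = FALSE)
      members[[length(members) + 1L]] <- sel
    }
  }
  res <- do.call(rbind, out)
  attr(res, "members") <- members
  res
}

# Overlap length of two closed intervals, negative gap when disjoint.
interval_overlap <- function(s1, e1, s2, e2) {
  pmin(e1, e2) - pmax(s1, s2)
}

#' One-to-one matching of noncoding blocks between two datasets
#'
#' Blocks from dataset B must already be mapped into A's coordinate system
#' (e.g. via a precomputed LiftOver table). Matching is greedy: candidate
#' pairs on the same chromosome are ranked by overlap length (descending),
#' then by distance (ascending), and each block is used at most once. A
#' pair with neither overlap nor a gap below `max_gap` never matches. The
#' joint presence of blocks is cross-classified over a universe of
#' candidate block positions and tested by Pearson chi-square.
#'
#' @param blocks_a,blocks_b data.frames with `chrom`, `start`, `end`.
#' @param universe total number of candidate blocks considered.
#' @param max_gap maximum gap in bp for a non-overlapping match.
#' @return list: `matches` (data.frame a, b, overlap, distance),
#'   `n_shared`, `table` (2x2), `statistic`, `df`, `p.value`.
#' @export
match_blocks_one_to_one <- function(blocks_a, blocks_b, universe,
                                    max_gap = 0) {
  stopifnot(is.data.frame(blocks_a), is.data.frame(blocks_b))
  cand <- list()
  for (i in seq_len(nrow(blocks_a))) {
    js <- which(blocks_b$chrom == blocks_a$chrom[i])
    for (j in js) {
      ov <- interval_overlap(blocks_a$start[i], blocks_a$end[i],
                             blocks_b$start[j], blocks_b$end[j])
      if (ov >= -max_gap)
        cand[[length(cand) + 1L]] <- data.frame(
          a = i, b = j, overlap = max(ov, 0), distance = max(-ov, 0))
    }
  }
  matches <- data.frame(a = integer(0), b = integer(0),
                        overlap = numeric(0), distance = numeric(0))
  if (length(cand) > 0L) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand$overlap, cand$distance), , drop = FALSE]
    used_a <- logical(nrow(blocks_a)); used_b <- logical(nrow(blocks_b))
    for (k in seq_len(nrow(cand))) {
      if (!used_a[cand$a[k]] && !used_b[cand$b[k]]) {
        matches <- rbind(matches, cand[k, ])
        used_a[cand$a[k]] <- TRUE; used_b[cand$b[k]] <- TRUE
      }
    }
  }
  n_shared <- nrow(matches)
  n_a_only <- nrow(blocks_a) - n_shared
  n_b_only <- nrow(blocks_b) - n_shared
  n_neither <- universe - n_shared - n_a_only - n_b_only
  if (n_neither < 0)
    stop("universe (", universe, ") smaller than the observed block union (",
         n_shared + n_a_only + n_b_only, ")")
  tab <- matrix(c(n_neither, n_a_only, n_b_only, n_shared), 2L, 2L,
                dimnames = list(in_a = c("no", "yes"), in_b = c("no", "yes")))
  cs <- chisq_2x2(tab)
  list(matches = matches, n_shared = n_shared, table = tab,
       statistic = cs$statistic, df = cs$df, p.value = cs$p.value)
}

#' Sign concordance of cis effect sizes between two datasets
#'
#' Cross-classifies the sign of alpha in dataset A against dataset B over a
#' shared gene list and tests association by Pearson chi-square (1 df, no
#' continuity correction). Genes with alpha exactly 0 in either dataset are
#' excluded and reported.
#'
#' @param alpha_a,alpha_b named numeric vectors of effect sizes; names are
#'   gene ids and the shared set is used.
#' @return list: `table` (2x2, rows = sign in A), `statistic`, `df`,
#'   `p.value`, `n_shared`, `n_zero_dropped`.
#' @export
sign_concordance <- function(alpha_a, alpha_b) {
  shared <- intersect(names(alpha_a), names(alpha_b))
  if (length(shared) == 0L) stop("no shared genes")
  a <- alpha_a[shared]; b <- alpha_b[shared]
  nz <- a != 0 & b != 0
  a <- a[nz]; b <- b[nz]
  tab <- matrix(c(sum(a > 0 & b > 0), sum(a < 0 & b > 0),
                  sum(a > 0 & b < 0), sum(a < 0 & b < 0)), 2L, 2L,
                dimnames = list(sign_a = c("pos", "neg"),
                                sign_b = c("pos", "neg")))
  cs <- chisq_2x2(tab)
  list(table = tab, statistic = cs$statistic, df = cs$df,
       p.value = cs$p.value, n_shared = sum(nz),
       n_zero_dropped = sum(!nz))
}

#' Paired test of X-linked vs autosomal cis effect-size attenuation
#'
#' For each clone, cis effect sizes are averaged over genes whose nearest
#' marker shows a copy gain in that clone (normalized dosage above half the
#' class-specific mode-2 target), separately for autosomal and X-linked
#' (sex-chromosome) genes and separately for positive and negative alpha.
#' A paired t-test across clones (df = complete clones - 1) compares the
#' autosomal and X means within each sign; clones lacking gained X-linked
#' genes are dropped from the pairing.
#'
#' @param cis_records data.frame with columns `gene`, `marker`, `alpha`;
#'   one row per gene (e.g. each gene's best or nearest-marker cis record).
#' @param dosage normalized `dosage_matrix`.
#' @param genome `rh_genome` giving each gene's chromosome class.
#' @return list with elements `positive` and `negative` (each: `statistic`,
#'   `df`, `p.value`, `mean_autosome`, `mean_x`, `n_clones`), plus
#'   `mean_abs_autosome`, `mean_abs_x` (unpaired |alpha| means) and
#'   `n_dropped_clones`.
#' @export
x_attenuation_test <- function(cis_records, dosage, genome) {
  stopifnot(is.data.frame(cis_records),
            all(c("gene", "marker", "alpha") %in% names(cis_records)),
            inherits(dosage, "dosage_matrix"), inherits(genome, "rh_genome"))
  g <- genome$genes
  cls <- genome$chromosomes$class[match(g$chrom, genome$chromosomes$name)]
  rec_cls <- cls[match(cis_records$gene, g$id)]
  if (anyNA(rec_cls)) stop("record gene missing from genome annotation")
  midx <- match(cis_records$marker, dosage$markers$id)
  if (anyNA(midx)) stop("record marker missing from dosage matrix")
  gain_thr <- norm_target(dosage$markers$class[midx]) / 2
  gained <- dosage$values[midx, , drop = FALSE] > gain_thr  # records x clones

  clone_mean <- function(keep) {
    # per-clone mean alpha over gained records in `keep`
    vapply(seq_len(ncol(gained)), function(cl) {
      sel <- keep & gained[, cl]
      if (!any(sel)) NA_real_ else mean(cis_records$alpha[sel])
    }, numeric(1))
  }
  paired <- function(sign_keep) {
    auto <- clone_mean(sign_keep & rec_cls == "autosome")
    xx <- clone_mean(sign_keep & rec_cls == "sex")
    ok <- is.finite(auto) & is.finite(xx)
    if (sum(ok) < 3L)
      return(list(statistic = NA_real_, df = NA_integer_, p.value = NA_real_,
                  mean_autosome = mean(auto, na.rm = TRUE),
                  mean_x = mean(xx, na.rm = TRUE), n_clones = sum(ok)))
    d <- auto[ok] - xx[ok]
    n <- length(d)
    t <- mean(d) / (stats::sd(d) / sqrt(n))
    list(statistic = t, df = n - 1L,
         p.value = 2 * stats::pt(abs(t), n - 1L, lower.tail = FALSE),
         mean_autosome = mean(auto[ok]), mean_x = mean(xx[ok]), n_clones = n)
  }
  pos <- paired(cis_records$alpha > 0)
  neg <- paired(cis_records$alpha < 0)
  auto_all <- clone_mean(rec_cls == "autosome")
  x_all <- clone_mean(rec_cls == "sex")
  list(positive = pos, negative = neg,
       mean_abs_autosome = mean(abs(cis_records$alpha[rec_cls == "autosome"])),
       mean_abs_x = mean(abs(cis_records$alpha[rec_cls == "sex"])),
       n_dropped_clones = sum(!(is.finite(auto_all) & is.finite(x_all))))
}

#' Chi-square comparison of binned trans-regulation landscapes
#'
#' Bins the genome into fixed-width windows, counts distinct regulated
#' genes per bin in each dataset, classifies bins as above/below each
#' dataset's median count, and tests the 2x2 cross-classification by
#' Pearson chi-square.
#'
#' @param records_a,records_b trans ceQTL data.frames in shared coordinates
#'   (columns `gene`, `marker_chrom`, `marker_pos`).
#' @param bin bin width in bp.
#' @return list: `table`, `statistic`, `df`, `p.value`, `bin_counts`
#'   (data.frame bin, count_a, count_b).
#' @export
binned_hotspot_overlap <- function(records_a, records_b, bin = 1e6) {
  count_bins <- function(r) {
    key <- paste0(r$marker_chrom, ":", floor(r$marker_pos / bin))
    tapply(r$gene, key, function(v) length(unique(v)))
  }
  ca <- count_bins(records_a); cb <- count_bins(records_b)
  bins <- union(names(ca), names(cb))
  df <- data.frame(bin = bins,
                   count_a = ifelse(bins %in% names(ca), ca[bins], 0),
                   count_b = ifelse(bins %in% names(cb), cb[bins], 0),
                   row.names = NULL, stringsAsFactors = FALSE)
  hi_a <- df$count_a > stats::median(df$count_a)
  hi_b <- df$count_b > stats::median(df$count_b)
  tab <- table(factor(hi_a, c(FALSE, TRUE)), factor(hi_b, c(FALSE, TRUE)))
  tab <- matrix(as.numeric(tab), 2L, 2L,
                dimnames = list(a_high = c("no", "yes"),
                                b_high = c("no", "yes")))
  cs <- chisq_2x2(tab)
  list(table = tab, statistic = cs$statistic, df = cs$df,
       p.value = cs$p.value, bin_counts = df)
}

#' Assign each peak to its closest gene
#'
#' The gene with minimal boundary distance on the peak's chromosome; exact
#' ties are broken toward the gene with the lower start coordinate and
#' flagged.
#'
#' @param peaks data.frame with `chrom`, `pos`.
#' @param genes data.frame with `id`, `chrom`, `start`, `end`.
#' @return data.frame: chrom, pos, gene, distance, tie.
#' @export
closest_gene_assignment <- function(peaks, genes) {
  stopifnot(is.data.frame(peaks), is.data.frame(genes))
  out <- lapply(seq_len(nrow(peaks)), function(i) {
    g <- genes[genes$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L)
      return(data.frame(chrom = peaks$chrom[i], pos = peaks$pos[i],
                        gene = NA_character_, distance = Inf, tie = FALSE,
                        stringsAsFactors = FALSE))
    d <- point_interval_distance(peaks$pos[i], g$start, g$end)
    best <- which(d == min(d))
    tie <- length(best) > 1L
    if (tie) best <- best[order(g$start[best])]
    data.frame(chrom = peaks$chrom[i], pos = peaks$pos[i],
               gene = g$id[best[1L]], distance = min(d), tie = tie,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
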