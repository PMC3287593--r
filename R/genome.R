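#' Genome definition for a radiation hybrid panel
#'
#' Bundles the coordinate system every other module works in: chromosome
#' sizes and classes (autosome vs sex), optional centromere intervals, the
#' selectable-marker locus that every surviving clone must retain (the
#' thymidine-kinase locus in classic TK-selected panels), aCGH marker
#' positions, and gene intervals. All coordinates are 0-based, half-open.
#'
#' @param chromosomes data.frame with columns `name`, `length` (bp) and
#'   `class` (`"autosome"` or `"sex"`).
#' @param markers data.frame with columns `id`, `chrom`, `pos` (bp); positions
#'   must be strictly increasing within a chromosome.
#' @param genes data.frame with columns `id`, `chrom`, `start`, `end` (bp).
#' @param selectable_locus list with elements `chrom` and `pos`: the locus
#'   under selection, retained by construction in every clone.
#' @param centromeres optional data.frame with columns `chrom`, `start`,
#'   `end` (bp).
#' @return an object of class `rh_genome`.
#' @export
rh_genome <- function(chromosomes, markers, genes, selectable_locus,
                      centromeres = NULL) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length", "class") %in% names(chromosomes)))
  if (anyDuplicated(chromosomes$name)) stop("duplicated chromosome names")
  if (!all(chromosomes$class %in% c("autosome", "sex")))
    stop("chromosome class must be 'autosome' or 'sex'")
  if (any(chromosomes$length <= 0)) stop("chromosome lengths must be positive")

  stopifnot(is.data.frame(markers), all(c("id", "chrom", "pos") %in% names(markers)))
  if (anyDuplicated(markers$id)) stop("duplicated marker ids")
  if (!all(markers$chrom %in% chromosomes$name))
    stop("marker on undefined chromosome: ",
         paste(unique(setdiff(markers$chrom, chromosomes$name)), collapse = ", "))
  chrlen <- stats::setNames(chromosomes$length, chromosomes$name)
  if (any(markers$pos < 0) || any(markers$pos >= chrlen[markers$chrom]))
    stop("marker position outside chromosome bounds")
  for (ch in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("marker positions not strictly increasing on ", ch)
  }

  stopifnot(is.data.frame(genes),
            all(c("id", "chrom", "start", "end") %in% names(genes)))
  if (anyDuplicated(genes$id)) stop("duplicated gene ids")
  if (!all(genes$chrom %in% chromosomes$name))
    stop("gene on undefined chromosome")
  if (any(genes$start < 0) || any(genes$end > chrlen[genes$chrom]) ||
      any(genes$end <= genes$start))
    stop("invalid gene interval")

  stopifnot(is.list(selectable_locus),
            all(c("chrom", "pos") %in% names(selectable_locus)))
  if (!selectable_locus$chrom %in% chromosomes$name)
    stop("selectable-marker locus on undefined chromosome")
  if (selectable_locus$pos < 0 ||
      selectable_locus$pos >= chrlen[[selectable_locus$chrom]])
    stop("selectable-marker locus outside chromosome bounds")

  if (!is.null(centromeres)) {
    stopifnot(is.data.frame(centromeres),
              all(c("chrom", "start", "end") %in% names(centromeres)))
    if (!all(centromeres$chrom %in% chromosomes$name))
      stop("centromere on undefined chromosome")
    if (any(centromeres$end <= centromeres$start))
      stop("invalid centromere interval")
  }

  markers$class <- chromosomes$class[match(markers$chrom, chromosomes$name)]
  structure(list(chromosomes = chromosomes, markers = markers, genes = genes,
                 selectable_locus = selectable_locus, centromeres = centromeres),
            class = "rh_genome")
}

#' @export
print.rh_genome <- function(x, ...) {
  cat("rh_genome:", nrow(x$chromosomes), "chromosomes,",
      nrow(x$markers), "markers,", nrow(x$genes), "genes\n")
  cat("selectable locus:", x$selectable_locus$chrom, "at",
      x$selectable_locus$pos, "bp\n")
  invisible(x)
}

#' Build a compact synthetic genome for simulation and testing
#'
#' A desk-scale stand-in for a mammalian genome: a few autosomes plus one
#' X-like sex chromosome, evenly spaced aCGH markers, evenly spaced genes,
#' and a selectable-marker locus mid-way along the first autosome. Marker
#' spacing should stay well below the donor fragment length (4 Mb by
#' default) so that sliding-window smoothing does not blur fragment
#' boundaries away, mirroring the high marker density of real aCGH panels.
#'
#' @param n_autosomes number of autosomes.
#' @param autosome_length,sex_length chromosome lengths in bp.
#' @param n_markers total marker count, split across chromosomes
#'   proportionally to length.
#' @param n_genes total gene count, split likewise; genes are 20 kb long.
#' @param centromere_fraction fraction of each chromosome, centered at 40%
#'   of its length, annotated as centromeric.
#' @return an `rh_genome`.
#' @export
example_genome <- function(n_autosomes = 3, autosome_length = 6e7,
                           sex_length = 6e7, n_markers = 2000,
                           n_genes = 200, centromere_fraction = 0.05) {
  chroms <- data.frame(
    name = c(paste0("chr", seq_len(n_autosomes)), "chrX"),
    length = as.numeric(c(rep(autosome_length, n_autosomes), sex_length)),
    class = c(rep("autosome", n_autosomes), "sex"),
    stringsAsFactors = FALSE)
  total <- sum(chroms$length)

  alloc <- function(n) {
    k <- pmax(1L, round(n * chroms$length / total))
    k[1] <- k[1] + (n - sum(k))  # make counts add up exactly
    k
  }
  nm <- alloc(n_markers)
  markers <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
    pos <- round(seq(0.5, nm[i] - 0.5) / nm[i] * chroms$length[i])
    data.frame(id = sprintf("%s_m%04d", chroms$name[i], seq_len(nm[i])),
               chrom = chroms$name[i], pos = pos, stringsAsFactors = FALSE)
  }))
  ng <- alloc(n_genes)
  genes <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
    start <- round(seq(0.5, ng[i] - 0.5) / ng[i] * (chroms$length[i] - 2e4))
    data.frame(id = sprintf("%s_g%03d", chroms$name[i], seq_len(ng[i])),
               chrom = chroms$name[i], start = start, end = start + 2e4,
               stringsAsFactors = FALSE)
  }))
  cen <- data.frame(
    chrom = chroms$name,
    start = round(chroms$length * (0.4 - centromere_fraction / 2)),
    end = round(chroms$length * (0.4 + centromere_fraction / 2)),
    stringsAsFactors = FALSE)
  rh_genome(chroms, markers, genes,
            selectable_locus = list(chrom = "chr1",
                                    pos = round(autosome_length / 2)),
            centromeres = cen)
}

#' Nearest marker to each gene
#'
#' Distance is measured from the gene interval (0 if the marker falls inside
#' the gene); only markers on the gene's chromosome are considered.
#'
#' @param genome an `rh_genome`.
#' @return character vector of marker ids, named by gene id.
#' @export
nearest_marker <- function(genome) {
  g <- genome$genes; m <- genome$markers
  out <- character(nrow(g))
  for (i in seq_len(nrow(g))) {
    idx <- which(m$chrom == g$chrom[i])
    if (length(idx) == 0L)
      stop("gene ", g$id[i], " has no marker on its chromosome")
    d <- point_interval_distance(m$pos[idx], g$start[i], g$end[i])
    out[i] <- m$id[idx[which.min(d)]]
  }
  stats::setNames(out, g$id)
}
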