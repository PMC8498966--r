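#' Do two half-open genomic intervals overlap by at least 1 bp?
#'
#' Intervals are 0-based half-open, so `[100, 200)` and `[200, 300)` touch
#' but do not overlap.
#'
#' @param chrom_a,start_a,end_a,chrom_b,start_b,end_b Interval coordinates
#'   (vectorised).
#' @return Logical vector: same chromosome and `max(starts) < min(ends)`.
#' @examples
#' intervals_overlap("chr1", 100, 200, "chr1", 199, 300)  # TRUE, 1 bp
#' intervals_overlap("chr1", 100, 200, "chr1", 200, 300)  # FALSE
#' @export
intervals_overlap <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  chrom_a == chrom_b & pmax(start_a, start_b) < pmin(end_a, end_b)
}

#' Count colocalization events between two peak tracks
#'
#' A colocalization event is an instance of >= 1 bp overlap between a peak
#' of one feature and a peak of the other. By default each intersecting
#' (peak A, peak B) pair counts as one event, so one A peak spanning two B
#' peaks yields two events; `mode = "merged-loci"` instead counts the
#' merged genomic loci where the two tracks intersect. Both modes are
#' symmetric in their arguments.
#'
#' @param track_a,track_b Peak track tibbles.
#' @param mode `"pairs"` (default) or `"merged-loci"`.
#' @return Integer event count.
#' @examples
#' a <- toy_track(tibble::tribble(~chrom, ~start, ~end, "chr1", 0, 100))
#' b <- toy_track(tibble::tribble(~chrom, ~start, ~end, "chr1", 50, 150))
#' count_colocalizations(a, b)
#' @export
count_colocalizations <- function(track_a, track_b, mode = c("pairs", "merged-loci")) {
  mode <- match.arg(mode)
  check_track(track_a, "track_a"); check_track(track_b, "track_b")
  if (nrow(track_a) == 0L || nrow(track_b) == 0L) return(0L)
  gr_a <- as_granges(track_a)
  gr_b <- as_granges(track_b)
  if (mode == "pairs") {
    length(GenomicRanges::findOverlaps(gr_a, gr_b, minoverlap = 1L))
  } else {
    length(GenomicRanges::reduce(GenomicRanges::intersect(
      GenomicRanges::reduce(gr_a), GenomicRanges::reduce(gr_b))))
  }
}

#' Strand-aware promoter windows around gene TSSs
#'
#' The promoter window runs from `upstream` bp upstream to `downstream` bp
#' downstream of the TSS on the gene's strand (defaults 3 kb / 10 kb, i.e. a
#' 13 kb window). For a minus-strand gene "upstream" lies to the right of
#' the TSS. Windows are clipped at position 0; genes whose clipped window
#' would be empty are dropped with a warning.
#'
#' @param genes Gene model tibble (see [read_genes()]).
#' @param upstream,downstream Window extent in bp on either side of the TSS.
#' @return Tibble `gene_id`, `chrom`, `strand`, `window_start`, `window_end`.
#' @examples
#' g <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "-",
#'                     start = 40000, end = 50000, tss = 50000)
#' promoter_windows(g)  # [40000, 53000)
#' @export
promoter_windows <- function(genes, upstream = 3000, downstream = 10000) {
  win <- genes |>
    mutate(
      window_start = if_else(.data$strand == "+", .data$tss - upstream, .data$tss - downstream),
      window_end = if_else(.data$strand == "+", .data$tss + downstream, .data$tss + upstream),
      window_start = pmax(.data$window_start, 0)
    ) |>
    select("gene_id", "chrom", "strand", "window_start", "window_end")
  empty <- win$window_end <= win$window_start
  if (any(empty)) {
    warn(glue::glue("dropping {sum(empty)} gene(s) whose clipped promoter window is empty"))
    win <- win[!empty, ]
  }
  win
}

#' Aggregate peak signal over gene promoter windows
#'
#' Maps every peak overlapping (>= 1 bp) a gene's promoter window to that
#' gene and sums, per gene: total signal `x` (the sum of `total_signal`
#' over mapped peaks), total peak width `w`, and peak count `k`. A peak
#' overlapping two genes' windows contributes its full signal to both.
#' Genes with no promoter peak get `x = w = k = 0`.
#'
#' @param track Peak track tibble.
#' @param genes Gene model tibble.
#' @param upstream,downstream Promoter window extent, see [promoter_windows()].
#' @return Tibble `gene_id`, `feature`, `x`, `w`, `k`, one row per gene, in
#'   the gene order of `genes`.
#' @export
map_peaks_to_promoters <- function(track, genes, upstream = 3000, downstream = 10000) {
  check_track(track)
  win <- promoter_windows(genes, upstream, downstream)
  out <- tibble(gene_id = win$gene_id,
                feature = if (nrow(track) > 0) track$feature[1] else NA_character_,
                x = 0, w = 0, k = 0L)
  if (nrow(track) > 0) {
    hits <- GenomicRanges::findOverlaps(
      as_granges(track),
      GenomicRanges::GRanges(win$chrom, IRanges::IRanges(win$window_start + 1, win$window_end)),
      minoverlap = 1L)
    if (length(hits) > 0) {
      agg <- tibble(gene = S4Vectors::subjectHits(hits), peak = S4Vectors::queryHits(hits)) |>
        group_by(.data$gene) |>
        summarise(x = sum(track$total_signal[.data$peak]),
                  w = sum(track$width[.data$peak]),
                  k = dplyr::n(), .groups = "drop")
      out$x[agg$gene] <- agg$x
      out$w[agg$gene] <- agg$w
      out$k[agg$gene] <- agg$k
    }
  }
  out
}

#' Which genes have the two features colocalized in their promoter?
#'
#' A gene counts as colocalized when some peak of feature A overlaps some
#' peak of feature B by >= 1 bp and the shared locus overlaps the gene's
#' promoter window.
#'
#' @inheritParams map_peaks_to_promoters
#' @param track_a,track_b Peak track tibbles for the two features.
#' @return Tibble `gene_id`, `colocalized` (logical).
#' @export
promoter_colocalization <- function(track_a, track_b, genes,
                                    upstream = 3000, downstream = 10000) {
  check_track(track_a, "track_a"); check_track(track_b, "track_b")
  win <- promoter_windows(genes, upstream, downstream)
  out <- tibble(gene_id = win$gene_id, colocalized = FALSE)
  if (nrow(track_a) == 0L || nrow(track_b) == 0L) return(out)
  shared <- GenomicRanges::intersect(
    GenomicRanges::reduce(as_granges(track_a)),
    GenomicRanges::reduce(as_granges(track_b)))
  if (length(shared) == 0L) return(out)
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(win$chrom, IRanges::IRanges(win$window_start + 1, win$window_end)),
    shared, minoverlap = 1L)
  out$colocalized[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}

#' Chunk peaks into consecutive width-ranked groups
#'
#' Peaks are sorted by width descending (ties broken by `(chrom, start)`
#' ascending) and chunked into consecutive groups of `group_size`; group 1
#' contains the widest peaks and the last group may be smaller.
#'
#' @param track Peak track tibble.
#' @param group_size Peaks per group (>= 1).
#' @return The track sorted by width descending with columns `width_rank`
#'   and `group` (integer, 1 = widest group) added.
#' @export
width_rank_groups <- function(track, group_size = 500) {
  check_track(track)
  stopifnot(group_size >= 1)
  track |>
    arrange(desc(.data$width), .data$chrom, .data$start) |>
    mutate(width_rank = row_number(),
           group = as.integer((row_number() - 1L) %/% group_size + 1L))
}

# small helper used in examples/tests: minimal valid track from coordinates
#' Build a minimal peak track from a coordinate tibble
#'
#' Fills in `strand`, `width`, and (when absent) width-valued signal columns
#' so toy tracks can be written inline. Intended for examples and tests.
#'
#' @param coords Tibble with at least `chrom`, `start`, `end`; optional
#'   `height`, `total_signal`, `strand`.
#' @param feature,cell_type Track labels.
#' @return A sorted peak track tibble.
#' @export
toy_track <- function(coords, feature = "feature", cell_type = "toy") {
  coords |>
    as_tibble() |>
    mutate(width = .data$end - .data$start,
           strand = if ("strand" %in% names(coords)) .data$strand else "*",
           height = if ("height" %in% names(coords)) .data$height else .data$width,
           total_signal = if ("total_signal" %in% names(coords)) .data$total_signal else .data$width,
           feature = feature, cell_type = cell_type) |>
    select("feature", "cell_type", "chrom", "start", "end", "strand",
           "height", "total_signal", "width") |>
    arrange(.data$chrom, .data$start, .data$end)
}
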