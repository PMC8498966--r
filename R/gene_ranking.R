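#' Rank genes by total promoter peak width of one marker
#'
#' Rank 1 is the gene with the largest summed peak width in its promoter
#' window; ties are broken by `gene_id` ascending, so the ranks are always
#' a permutation of `1..n`. Genes with zero width sort last.
#'
#' @param signals Per-gene signal tibble from [map_peaks_to_promoters()]
#'   (column `w`).
#' @return The tibble with a `width_rank` column added, sorted by rank.
#' @examples
#' s <- tibble::tibble(gene_id = c("g1", "g2", "g3"), w = c(100, 300, 200))
#' rank_by_width(s)$width_rank  # g2 = 1, g3 = 2, g1 = 3
#' @export
rank_by_width <- function(signals) {
  stopifnot("w" %in% names(signals), nrow(signals) >= 1)
  signals |>
    arrange(desc(.data$w), .data$gene_id) |>
    mutate(width_rank = row_number())
}

#' Rank genes by the rank product of two markers' promoter widths
#'
#' Each gene's rank product is the product of its two width ranks,
#' `RP = r1 * r2`; small values mark genes jointly broad in both markers.
#' Genes where the two markers do not colocalize (no >= 1 bp peak overlap
#' within the promoter window) are removed from the ranking.
#'
#' @param sig_a,sig_b Per-gene signal tibbles for the two markers over the
#'   same gene universe.
#' @param colocalized Tibble `gene_id`, `colocalized` from
#'   [promoter_colocalization()], or `NULL` to keep all genes.
#' @return Tibble `gene_id`, `w_a`, `w_b`, `rank_a`, `rank_b`,
#'   `rank_product`, sorted by rank product ascending (ties: `gene_id`).
#' @export
rank_product <- function(sig_a, sig_b, colocalized = NULL) {
  align_genes(sig_a, sig_b)
  ra <- rank_by_width(sig_a) |> select("gene_id", w_a = "w", rank_a = "width_rank")
  rb <- rank_by_width(sig_b) |> select("gene_id", w_b = "w", rank_b = "width_rank")
  out <- inner_join(ra, rb, by = "gene_id") |>
    mutate(rank_product = .data$rank_a * .data$rank_b)
  if (!is.null(colocalized)) {
    keep <- colocalized$gene_id[colocalized$colocalized]
    out <- filter(out, .data$gene_id %in% keep)
  }
  arrange(out, .data$rank_product, .data$gene_id)
}

#' Top-N genes of a ranked table
#'
#' The first `n` genes of an already-sorted ranked table (all of them, with
#' a warning, when fewer than `n` are available). Deterministic under the
#' ranking's documented tie-breaks, and idempotent.
#'
#' @param table A ranked gene tibble (sorted).
#' @param n Group size (default 500).
#' @return Character vector of gene ids.
#' @export
top_genes <- function(table, n = 500) {
  stopifnot("gene_id" %in% names(table), n >= 0)
  if (n > nrow(table)) {
    warn(glue::glue("requested top {n} genes but only {nrow(table)} available"))
  }
  head(table$gene_id, n)
}

#' Intersection size and percentage of two gene sets
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @param denominator Denominator for the percentage (e.g. the group
#'   size, 500).
#' @return One-row tibble: `n_intersection`, `percent` (one decimal),
#'   `percent_int` (integer rounding, as percentages are usually quoted in
#'   prose).
#' @examples
#' set_overlap_stats(as.character(1:288), as.character(1:500), 500)  # 57.6%
#' @export
set_overlap_stats <- function(set_a, set_b, denominator) {
  stopifnot(denominator > 0)
  n_int <- length(intersect(set_a, set_b))
  pct <- 100 * n_int / denominator
  tibble(n_intersection = n_int, percent = round(pct, 1), percent_int = round(pct))
}

#' Marker presence in each gene's promoter or gene body
#'
#' A marker is present for a gene when at least one peak of the track
#' overlaps the queried region by >= 1 bp. Combining presence calls across
#' cell types gives the lost-in-both / retained-in-both summaries: a gene
#' "lost" a marker when it is absent in every queried track, and "retained"
#' it when present in all of them.
#'
#' @param genes Gene model tibble.
#' @param track Peak track tibble for one marker in one cell type.
#' @param region `"promoter"` (default window, see [promoter_windows()]) or
#'   `"gene-body"`.
#' @param upstream,downstream Promoter window extent (promoter region only).
#' @return Tibble `gene_id`, `present` (logical).
#' @export
marker_presence <- function(genes, track, region = c("promoter", "gene-body"),
                            upstream = 3000, downstream = 10000) {
  region <- match.arg(region)
  check_track(track)
  if (region == "promoter") {
    win <- promoter_windows(genes, upstream, downstream)
    gr <- GenomicRanges::GRanges(win$chrom,
                                 IRanges::IRanges(win$window_start + 1, win$window_end))
    ids <- win$gene_id
  } else {
    gr <- as_granges(genes)
    ids <- genes$gene_id
  }
  present <- rep(FALSE, length(ids))
  if (nrow(track) > 0) {
    hits <- GenomicRanges::findOverlaps(gr, as_granges(track), minoverlap = 1L)
    present[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  tibble(gene_id = ids, present = present)
}

#' Lost / retained status of a gene set across cell types
#'
#' @param gene_set Character vector of gene ids (e.g. top CSE genes).
#' @param genes Gene model tibble.
#' @param tracks List of peak track tibbles, one per comparison cell type.
#' @param region Passed to [marker_presence()].
#' @return One-row tibble: `n`, `n_lost_in_all`, `pct_lost`,
#'   `n_retained_in_all`, `pct_retained` (percent columns at one decimal,
#'   `*_int` at integer precision).
#' @export
marker_status_summary <- function(gene_set, genes, tracks,
                                  region = c("promoter", "gene-body")) {
  region <- match.arg(region)
  pres <- purrr::map(tracks, function(tr) {
    marker_presence(genes, tr, region = region) |>
      filter(.data$gene_id %in% gene_set)
  })
  mat <- do.call(cbind, purrr::map(pres, "present"))
  n <- length(gene_set)
  lost <- sum(rowSums(mat) == 0)
  kept <- sum(rowSums(mat) == ncol(mat))
  tibble(n = n,
         n_lost_in_all = lost, pct_lost = round(100 * lost / n, 1),
         pct_lost_int = round(100 * lost / n),
         n_retained_in_all = kept, pct_retained = round(100 * kept / n, 1),
         pct_retained_int = round(100 * kept / n))
}
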