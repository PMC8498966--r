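#' High-confidence peaks: height above the upper quartile
#'
#' Keeps peaks whose height is strictly greater than the upper quartile
#' (Q3, linear-interpolation type-7 quantile) of the track's peak heights.
#' With all heights equal nothing survives the strict comparison.
#'
#' @param track Peak track tibble (typically CTCF).
#' @return The filtered track; the threshold is attached as attribute
#'   `"hc_threshold"`.
#' @examples
#' tr <- toy_track(tibble::tibble(chrom = "chr1", start = 0:7 * 1000,
#'                                end = 0:7 * 1000 + 100, height = 1:8))
#' high_confidence_peaks(tr)  # Q3 = 6.25, keeps heights 7 and 8
#' @export
high_confidence_peaks <- function(track) {
  check_track(track)
  if (nrow(track) == 0) {
    warn("empty track: no high-confidence peaks")
    return(structure(track, hc_threshold = NA_real_))
  }
  if (nrow(track) < 4) warn("fewer than 4 peaks: upper-quartile threshold is unstable")
  q3 <- unname(quantile(track$height, 0.75, type = 7))
  out <- filter(track, .data$height > q3)
  if (nrow(out) == 0) warn("no peak height strictly exceeds the upper quartile")
  structure(out, hc_threshold = q3)
}

#' Stitch peaks into enhancers
#'
#' Merges peaks whose gap is at most `stitch_distance` bp into stitched
#' enhancer regions (ROSE-style), summing constituent signal. Stitching is
#' idempotent.
#'
#' @param track H3K27ac peak track tibble.
#' @param stitch_distance Maximum gap bridged, in bp (default 12500).
#' @return Tibble `chrom`, `start`, `end`, `width`, `total_signal`,
#'   `n_peaks`, sorted by coordinates.
#' @export
stitch_peaks <- function(track, stitch_distance = 12500) {
  check_track(track)
  gr <- as_granges(track)
  merged <- GenomicRanges::reduce(gr, min.gapwidth = stitch_distance + 1)
  hits <- GenomicRanges::findOverlaps(gr, merged)
  tibble(chrom = as.character(GenomicRanges::seqnames(merged)),
         start = GenomicRanges::start(merged) - 1,
         end = GenomicRanges::end(merged)) |>
    mutate(width = .data$end - .data$start,
           total_signal = as.vector(tapply(track$total_signal,
                                           S4Vectors::subjectHits(hits), sum)),
           n_peaks = as.integer(table(S4Vectors::subjectHits(hits)))) |>
    arrange(.data$chrom, .data$start)
}

#' Call super-enhancers by the rank-signal inflection
#'
#' Peaks are stitched (see [stitch_peaks()]), stitched enhancers ranked by
#' total signal ascending, and both rank and signal scaled to `[0, 1]`.
#' The cutoff sits where the tangent slope of the scaled rank-signal curve
#' first reaches 1; enhancers above the cutoff are super-enhancers.
#'
#' @param track H3K27ac peak track tibble.
#' @param stitch_distance Stitching gap in bp.
#' @return Tibble of stitched enhancers with `signal_rank` (1 = weakest),
#'   `is_super`, and attribute `"se_cutoff_index"` (the tangent index on
#'   the ascending curve; enhancers with `signal_rank` greater than it are
#'   super). Supports [autoplot_se_curve()].
#' @export
call_superenhancers <- function(track, stitch_distance = 12500) {
  enh <- stitch_peaks(track, stitch_distance) |>
    arrange(.data$total_signal, .data$chrom, .data$start) |>
    mutate(signal_rank = row_number())
  n <- nrow(enh)
  if (n < 3) {
    warn("fewer than 3 stitched enhancers: no inflection, all flagged not-super")
    return(structure(mutate(enh, is_super = FALSE), se_cutoff_index = NA_integer_))
  }
  cut_idx <- se_inflection_index(enh$total_signal)
  if (is.na(cut_idx)) warn("no reliable rank-signal inflection found")
  enh <- mutate(enh, is_super = !is.na(cut_idx) & .data$signal_rank > cut_idx)
  structure(enh, se_cutoff_index = cut_idx)
}

# internal: first index (on the ascending, scaled curve) whose forward
# tangent slope reaches 1; signals assumed sorted ascending
se_inflection_index <- function(signal) {
  n <- length(signal)
  smax <- max(signal)
  if (smax <= 0 || n < 2) return(NA_integer_)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- signal / smax
  slope <- diff(y) / diff(x)
  idx <- which(slope >= 1)
  if (length(idx) == 0) NA_integer_ else idx[1]
}

#' Classify super-enhancers by high-confidence CTCF co-binding
#'
#' A super-enhancer containing (>= 1 bp overlap) at least one
#' high-confidence CTCF peak is a CTCF-associated super-enhancer (CSE);
#' super-enhancers without one are other super-enhancers (OSE). Non-super
#' enhancers are labelled `"not-super"` regardless of CTCF.
#'
#' @param enhancers Enhancer calls from [call_superenhancers()].
#' @param hc_ctcf High-confidence CTCF track from [high_confidence_peaks()].
#' @return The enhancer tibble with `n_hc_ctcf` and `ctcf_class`
#'   (`"CSE"` / `"OSE"` / `"not-super"`) added. CSE and OSE partition the
#'   super-enhancers.
#' @export
classify_cse_ose <- function(enhancers, hc_ctcf) {
  stopifnot(all(c("chrom", "start", "end", "is_super") %in% names(enhancers)))
  n_hc <- if (nrow(hc_ctcf) == 0 || nrow(enhancers) == 0) {
    rep(0L, nrow(enhancers))
  } else {
    GenomicRanges::countOverlaps(as_granges(enhancers), as_granges(hc_ctcf),
                                 minoverlap = 1L)
  }
  enhancers |>
    mutate(n_hc_ctcf = as.integer(n_hc),
           ctcf_class = dplyr::case_when(
             !.data$is_super ~ "not-super",
             .data$n_hc_ctcf >= 1L ~ "CSE",
             TRUE ~ "OSE"))
}

#' Genes whose body overlaps an enhancer class
#'
#' A gene belongs to the CSE (or OSE) gene set when its gene body overlaps
#' a CSE (or OSE) by at least 1 bp. A gene overlapping both classes is
#' assigned to CSE (precedence rule, logged), so requesting OSE genes
#' excludes them. Genes are ordered by the total signal of their strongest
#' overlapping enhancer of the class, descending, so `head(..., n)` gives
#' the top-N genes of the class.
#'
#' @param enhancers Classified enhancer tibble from [classify_cse_ose()].
#' @param genes Gene model tibble.
#' @param class `"CSE"` or `"OSE"`.
#' @return Tibble `gene_id`, `best_enhancer_signal`, sorted descending.
#' @export
assign_enhancer_genes <- function(enhancers, genes, class = c("CSE", "OSE")) {
  class <- match.arg(class)
  stopifnot("ctcf_class" %in% names(enhancers))
  genes_of <- function(cls) {
    sub <- filter(enhancers, .data$ctcf_class == cls)
    if (nrow(sub) == 0) return(tibble(gene_id = character(), best_enhancer_signal = numeric()))
    hits <- GenomicRanges::findOverlaps(as_granges(genes), as_granges(sub), minoverlap = 1L)
    tibble(gene_id = genes$gene_id[S4Vectors::queryHits(hits)],
           signal = sub$total_signal[S4Vectors::subjectHits(hits)]) |>
      group_by(.data$gene_id) |>
      summarise(best_enhancer_signal = max(.data$signal), .groups = "drop") |>
      arrange(desc(.data$best_enhancer_signal), .data$gene_id)
  }
  out <- genes_of(class)
  if (class == "OSE") {
    both <- intersect(out$gene_id, genes_of("CSE")$gene_id)
    if (length(both) > 0) {
      inform(glue::glue("{length(both)} gene(s) overlap both CSE and OSE; assigned to CSE"))
      out <- filter(out, !.data$gene_id %in% both)
    }
  }
  out
}

#' Enlarge typical enhancers to matched super-enhancer widths
#'
#' The null simulation for CTCF association versus enhancer size: each
#' typical enhancer is randomly matched to a super-enhancer (with
#' replacement) and grown symmetrically about its midpoint until it has the
#' matched super-enhancer's width. Growth past position 0 is clipped, the
#' deficit moving to the other side, so widths always match exactly.
#'
#' @param typical,supers Enhancer tibbles (`chrom`, `start`, `end`), both
#'   non-empty.
#' @param ctcf Optional CTCF peak track; when given, the fraction of each
#'   collection (typical, enlarged, super) overlapping >= 1 CTCF peak is
#'   reported.
#' @param seed Optional integer seed for the matching.
#' @return List with `enlarged` (the typical tibble with new coordinates
#'   and `matched_width`) and `association` (one row per collection with
#'   `ctcf_fraction`, or `NULL` without `ctcf`).
#' @export
enlarge_typical_enhancers <- function(typical, supers, ctcf = NULL, seed = NULL) {
  stopifnot(nrow(typical) > 0, nrow(supers) > 0)
  if (!is.null(seed)) set.seed(seed)
  match_idx <- sample.int(nrow(supers), nrow(typical), replace = TRUE)
  target_w <- (supers$end - supers$start)[match_idx]
  mid <- floor((typical$start + typical$end) / 2)
  new_start <- mid - floor(target_w / 2)
  new_end <- new_start + target_w
  clip <- pmax(0, -new_start)
  enlarged <- typical |>
    mutate(start = new_start + clip, end = new_end + clip,
           width = .data$end - .data$start, matched_width = target_w)
  association <- NULL
  if (!is.null(ctcf)) {
    frac <- function(tab) {
      if (nrow(tab) == 0) return(NA_real_)
      mean(GenomicRanges::countOverlaps(as_granges(tab), as_granges(ctcf),
                                        minoverlap = 1L) > 0)
    }
    association <- tibble(
      collection = c("typical", "enlarged_typical", "super"),
      ctcf_fraction = c(frac(typical), frac(enlarged), frac(supers)))
  }
  list(enlarged = enlarged, association = association)
}

#' Rank-signal curve of an enhancer call set
#'
#' The scaled rank-versus-signal hockey-stick with the super-enhancer
#' cutoff marked.
#'
#' @param enhancers Result of [call_superenhancers()].
#' @return A ggplot object.
#' @export
autoplot_se_curve <- function(enhancers) {
  n <- nrow(enhancers)
  df <- enhancers |>
    arrange(.data$signal_rank) |>
    mutate(x = (.data$signal_rank - 1) / max(1, n - 1),
           y = .data$total_signal / max(.data$total_signal))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$is_super)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "scaled signal rank", y = "scaled total signal",
                  colour = "super") +
    ggplot2::theme_minimal()
}

#' Write enhancer calls as BED6+ (name = class, score = total signal)
#' @param enhancers Classified enhancer tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enhancers_bed <- function(enhancers, path) {
  bed <- tibble(
    chrom = enhancers$chrom,
    start = format(enhancers$start, scientific = FALSE, trim = TRUE),
    end = format(enhancers$end, scientific = FALSE, trim = TRUE),
    name = if ("ctcf_class" %in% names(enhancers)) enhancers$ctcf_class
           else if_else(enhancers$is_super, "super", "typical"),
    score = enhancers$total_signal, strand = ".")
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
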