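#' Read a ChIP-seq peak file into a peak track tibble
#'
#' Parses BED3/BED6, ENCODE narrowPeak, or a headered TSV
#' (`chrom`, `start`, `end`, optionally `strand`, `height`, `total_signal`)
#' into the tabular peak model used throughout the package. All coordinates
#' are stored 0-based half-open (BED native); `width = end - start`.
#'
#' Signal mapping by format:
#' * `narrowPeak`: `height` is the `signalValue` column (column 7);
#'   `total_signal` is `signalValue * width` (narrowPeak stores no summed
#'   signal, so a uniform per-base profile is assumed).
#' * `tsv`: `height` and `total_signal` columns are taken as-is.
#' * `bed` (no signal columns): `height` and `total_signal` fall back to the
#'   peak width, with a message. Tracks read this way carry degenerate
#'   signal and are refused by [mutual_information()] unless explicitly
#'   allowed, because every "signal" is then just a width.
#'
#' @param path Path to the peak file.
#' @param format One of `"auto"`, `"bed"`, `"narrowPeak"`, `"tsv"`. `"auto"`
#'   picks narrowPeak for 10-column headerless files, TSV when a header with
#'   a `chrom` column is present, BED otherwise.
#' @param feature,cell_type Labels attached to every peak (columns `feature`
#'   and `cell_type`).
#' @return A tibble with columns `feature`, `cell_type`, `chrom`, `start`,
#'   `end`, `strand`, `height`, `total_signal`, `width`, sorted by
#'   `(chrom, start, end)`. Malformed comment/track lines are skipped and
#'   counted in a message.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t10\t60", "chr1\t5\t30", "chr1\t20\t90"), bed)
#' read_peaks(bed, feature = "H3K27ac", cell_type = "toy")
#' @export
read_peaks <- function(path, format = c("auto", "bed", "narrowPeak", "tsv"),
                       feature = "feature", cell_type = "cell_type") {
  format <- match.arg(format)
  if (!file.exists(path)) abort(glue::glue("peak file not found: {path}"))
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)|^\\s*$", lines)
  n_skipped <- sum(!keep)
  if (n_skipped > 0) inform(glue::glue("{path}: skipped {n_skipped} comment/track/empty line(s)"))
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0L) abort(glue::glue("{path}: no data lines"))

  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol1 <- length(fields[[1]])
  has_header <- "chrom" %in% fields[[1]]

  if (format == "auto") {
    format <- if (has_header) "tsv" else if (ncol1 >= 10) "narrowPeak" else "bed"
  }

  if (format == "tsv") {
    tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                           progress = FALSE)
    req <- c("chrom", "start", "end")
    if (!all(req %in% names(tab))) {
      abort(glue::glue("{path}: TSV format requires columns {toString(req)}"))
    }
    if (!all(c("height", "total_signal") %in% names(tab))) {
      abort(glue::glue("{path}: TSV peak format requires 'height' and 'total_signal' columns"))
    }
    peaks <- tibble(
      chrom = as.character(tab$chrom),
      start = as.numeric(tab$start),
      end = as.numeric(tab$end),
      strand = if ("strand" %in% names(tab)) as.character(tab$strand) else "*",
      height = as.numeric(tab$height),
      total_signal = as.numeric(tab$total_signal)
    )
    bad <- which(is.na(peaks$start) | is.na(peaks$end) | peaks$end <= peaks$start)
    if (length(bad) > 0) {
      abort(glue::glue("{path}: invalid interval (end <= start or non-numeric) at data row {bad[1]}"))
    }
  } else {
    nf <- lengths(fields)
    min_cols <- if (format == "narrowPeak") 10L else 3L
    short <- which(nf < min_cols)
    if (length(short) > 0) {
      abort(glue::glue("{path}: line {line_no[short[1]]}: expected >= {min_cols} columns, found {nf[short[1]]}"))
    }
    col <- function(i) vapply(fields, `[[`, "", i)
    chrom <- col(1)
    start <- suppressWarnings(as.numeric(col(2)))
    end <- suppressWarnings(as.numeric(col(3)))
    bad <- which(is.na(start) | is.na(end))
    if (length(bad) > 0) {
      abort(glue::glue("{path}: line {line_no[bad[1]]}: unparseable coordinates"))
    }
    bad <- which(end <= start)
    if (length(bad) > 0) {
      abort(glue::glue("{path}: line {line_no[bad[1]]}: end ({end[bad[1]]}) <= start ({start[bad[1]]})"))
    }
    strand <- if (max(nf) >= 6 && format != "narrowPeak") col(6) else
      if (format == "narrowPeak") col(6) else rep("*", length(chrom))
    strand[!strand %in% c("+", "-")] <- "*"
    width <- end - start
    if (format == "narrowPeak") {
      sigval <- suppressWarnings(as.numeric(col(7)))
      bad <- which(is.na(sigval))
      if (length(bad) > 0) {
        abort(glue::glue("{path}: line {line_no[bad[1]]}: missing/unparseable signalValue column"))
      }
      height <- sigval
      total_signal <- sigval * width
    } else {
      inform(glue::glue(
        "{path}: plain BED without signal columns; height and total_signal fall back to peak width"))
      height <- width
      total_signal <- width
    }
    peaks <- tibble(chrom = chrom, start = start, end = end, strand = strand,
                    height = height, total_signal = total_signal)
  }

  if (any(peaks$height < 0, na.rm = TRUE) || any(peaks$total_signal < 0, na.rm = TRUE)) {
    abort(glue::glue("{path}: negative signal values"))
  }
  peaks |>
    mutate(feature = feature, cell_type = cell_type, width = .data$end - .data$start) |>
    relocate("feature", "cell_type") |>
    arrange(.data$chrom, .data$start, .data$end)
}

#' Read a gene annotation into a gene model tibble
#'
#' Accepts BED12 (or any BED6+ with name and strand), GTF-like annotation
#' (1-based inclusive, converted to 0-based half-open on read), or a headered
#' TSS table (`gene_id`, `chrom`, `strand`, `tss`, optional `start`/`end`).
#' Every gene must carry a strand. Multi-transcript genes are collapsed to a
#' single representative: the most upstream TSS on the gene's strand
#' (minimum `start` for `+`, maximum `end` for `-`), with the union of
#' transcript extents as the gene body.
#'
#' @param path Annotation file path.
#' @param format `"auto"`, `"bed12"`, `"gtf"`, or `"tss"`.
#' @return A tibble with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end` (gene body, 0-based half-open) and `tss`. For `+` genes
#'   `tss == start`; for `-` genes `tss == end` (the boundary coordinate of
#'   the first transcribed base in half-open convention).
#' @export
read_genes <- function(path, format = c("auto", "bed12", "gtf", "tss")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(glue::glue("annotation not found: {path}"))
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)|^\\s*$", lines)
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0L) abort(glue::glue("{path}: no data lines"))
  first <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]

  if (format == "auto") {
    format <- if (identical(first[1], "gene_id") || "tss" %in% first) "tss"
    else if (length(first) >= 9 && grepl("gene_id", lines[[1]])) "gtf"
    else "bed12"
  }

  if (format == "tss") {
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    req <- c("gene_id", "chrom", "strand", "tss")
    if (!all(req %in% names(tab))) abort(glue::glue("{path}: TSS table requires columns {toString(req)}"))
    genes <- tibble(
      gene_id = as.character(tab$gene_id), chrom = as.character(tab$chrom),
      strand = as.character(tab$strand),
      start = if ("start" %in% names(tab)) as.numeric(tab$start) else as.numeric(tab$tss),
      end = if ("end" %in% names(tab)) as.numeric(tab$end) else as.numeric(tab$tss) + 1
    )
  } else if (format == "gtf") {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 9)) abort(glue::glue("{path}: line {line_no[which(nf < 9)[1]]}: expected 9 GTF columns"))
    col <- function(i) vapply(fields, `[[`, "", i)
    type <- col(3)
    use <- type %in% c("gene", "transcript", "mRNA")
    if (any(type == "transcript")) use <- type == "transcript"
    else if (any(type == "gene")) use <- type == "gene"
    if (!any(use)) abort(glue::glue("{path}: no gene/transcript records"))
    gid <- sub('.*gene_id[ =]+"?([^";]+)"?.*', "\\1", col(9))
    genes <- tibble(
      gene_id = gid[use], chrom = col(1)[use], strand = col(7)[use],
      # GTF is 1-based inclusive; shift start by -1 for half-open storage
      start = suppressWarnings(as.numeric(col(4)[use])) - 1,
      end = suppressWarnings(as.numeric(col(5)[use]))
    )
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 6)) abort(glue::glue("{path}: line {line_no[which(nf < 6)[1]]}: BED12 needs >= 6 columns (strand required)"))
    col <- function(i) vapply(fields, `[[`, "", i)
    genes <- tibble(
      gene_id = col(4), chrom = col(1), strand = col(6),
      start = suppressWarnings(as.numeric(col(2))),
      end = suppressWarnings(as.numeric(col(3)))
    )
  }

  bad <- which(is.na(genes$start) | is.na(genes$end) | genes$end <= genes$start)
  if (length(bad) > 0) abort(glue::glue("{path}: record {bad[1]}: invalid gene body coordinates"))
  if (!all(genes$strand %in% c("+", "-"))) {
    bad <- which(!genes$strand %in% c("+", "-"))[1]
    abort(glue::glue("{path}: record {bad}: missing or invalid strand '{genes$strand[bad]}'"))
  }

  n_dup <- sum(duplicated(genes$gene_id))
  if (n_dup > 0) inform(glue::glue("{path}: collapsing {n_dup} extra transcript record(s) to one TSS per gene"))
  genes |>
    group_by(.data$gene_id) |>
    summarise(chrom = .data$chrom[1], strand = .data$strand[1],
              start = min(.data$start), end = max(.data$end),
              .groups = "drop") |>
    mutate(tss = if_else(.data$strand == "+", .data$start, .data$end)) |>
    arrange(.data$chrom, .data$start)
}

#' Write / re-read a peak track as TSV
#'
#' The TSV round-trips exactly through [read_peaks()] with `format = "tsv"`:
#' coordinates and signals are written in full precision.
#'
#' @param track A peak track tibble (see [read_peaks()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_tsv <- function(track, path) {
  stopifnot(is.data.frame(track))
  readr::write_tsv(track, path, progress = FALSE)
  invisible(path)
}

#' Write a peak track as BED6 (name = feature, score = height)
#' @param track A peak track tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_bed <- function(track, path) {
  bed <- tibble(
    chrom = track$chrom, start = format(track$start, scientific = FALSE, trim = TRUE),
    end = format(track$end, scientific = FALSE, trim = TRUE),
    name = track$feature, score = track$height,
    strand = if_else(track$strand %in% c("+", "-"), track$strand, ".")
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Summarise a run's inputs as a JSON string
#'
#' @param tracks A named list of peak track tibbles.
#' @param genes Optional gene model tibble.
#' @return A JSON string with per-track peak counts and signal totals.
#' @export
run_summary_json <- function(tracks, genes = NULL) {
  summ <- purrr::imap(tracks, function(tr, nm) {
    list(track = nm, n_peaks = nrow(tr),
         total_signal = sum(tr$total_signal), mean_width = mean(tr$width))
  })
  jsonlite::toJSON(list(tracks = unname(summ),
                        n_genes = if (is.null(genes)) NULL else nrow(genes)),
                   auto_unbox = TRUE, digits = NA, null = "null")
}

# internal: peak/gene tibble -> GRanges (IRanges is 1-based inclusive)
as_granges <- function(tab) {
  GenomicRanges::GRanges(
    seqnames = tab$chrom,
    ranges = IRanges::IRanges(start = tab$start + 1, end = tab$end)
  )
}

# internal: validate the minimal peak-track contract
check_track <- function(track, arg = "track") {
  req <- c("chrom", "start", "end", "height", "total_signal", "width")
  if (!is.data.frame(track) || !all(req %in% names(track))) {
    abort(glue::glue("{arg} must be a peak track tibble with columns {toString(req)}"))
  }
  if (any(track$end <= track$start)) abort(glue::glue("{arg}: peak with end <= start"))
  invisible(track)
}

# internal: TRUE when signals are just widths (plain-BED fallback)
signal_is_degenerate <- function(track) {
  nrow(track) > 0 && all(track$total_signal == track$width) && all(track$height == track$width)
}
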