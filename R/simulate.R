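#' Simulate a multi-feature peak panel with planted correlation and colocalization
#'
#' Generates a toy genome, a strand-mixed gene annotation, and one peak
#' track per (cell type, feature), with two independently tunable planted
#' properties per feature pair:
#' * per-gene promoter signal correlation `rho`, planted through a Gaussian
#'   copula on the per-gene signal magnitudes;
#' * a target genome-wide colocalization count `c_star`, planted as
#'   dedicated overlapping peak pairs in intergenic stripes (midpoint
#'   copied between tracks with sub-width jitter), so each planted pair
#'   contributes exactly one >= 1 bp overlap event.
#'
#' Promoter peaks of different features occupy disjoint offsets inside the
#' 13 kb window and every pair's planted loci live in their own intergenic
#' stripe, so correlation and colocalization do not interfere — exactly the
#' regime where colocalization in excess of correlation is detectable.
#' Feasibility (features per window, stripes per gap, events per genome) is
#' checked before anything is generated or written.
#'
#' @param pair_targets Tibble `cell_type`, `feature_a`, `feature_b`, `rho`
#'   (in `[-1, 1]`), `c_star` (>= 0). Per cell type the implied feature
#'   correlation matrix must be positive semi-definite.
#' @param n_genes Genes on the toy genome (one shared annotation).
#' @param seed Integer seed; the panel is a pure function of its arguments.
#' @param mean_signal,sd_signal Gaussian signal magnitude parameters.
#' @param peak_width Promoter peak width in bp.
#' @param gene_spacing Gene slot size in bp (promoter window 13 kb +
#'   intergenic stripes).
#' @param dir Optional directory: writes one narrowPeak per track, a BED12
#'   annotation (`genes.bed12`), and a manifest TSV, deterministically.
#' @return List: `tracks` (named list of peak track tibbles,
#'   `cell_type:feature`), `genes`, `manifest`, `genome_length`,
#'   `pair_targets`.
#' @export
simulate_panel <- function(pair_targets, n_genes = 200, seed = 1,
                           mean_signal = 100, sd_signal = 20,
                           peak_width = 500, gene_spacing = 30000,
                           dir = NULL) {
  req <- c("cell_type", "feature_a", "feature_b", "rho", "c_star")
  stopifnot(all(req %in% names(pair_targets)), n_genes >= 2)
  if (any(abs(pair_targets$rho) > 1)) abort("rho must lie in [-1, 1]")
  if (any(pair_targets$c_star < 0)) abort("c_star must be >= 0")
  if (any(pair_targets$c_star > n_genes)) {
    abort("infeasible: c_star exceeds n_genes (one planted event per gene slot)")
  }

  by_ct <- split(pair_targets, pair_targets$cell_type)
  feat_of <- purrr::map(by_ct, ~ sort(unique(c(.x$feature_a, .x$feature_b))))
  if (any(lengths(feat_of) > 8)) {
    abort("infeasible: > 8 features per cell type do not fit the promoter window slots")
  }
  n_pairs_ct <- purrr::map_int(by_ct, nrow)
  stripe_w <- 1000
  if (any(n_pairs_ct * stripe_w > gene_spacing - 13500 - 700)) {
    abort("infeasible: too many pairs per cell type for the intergenic stripes")
  }
  # per-cell-type feature correlation matrices must be PSD
  sigmas <- purrr::imap(by_ct, function(tt, ct) {
    f <- feat_of[[ct]]
    s <- diag(length(f)); dimnames(s) <- list(f, f)
    for (i in seq_len(nrow(tt))) {
      s[tt$feature_a[i], tt$feature_b[i]] <- tt$rho[i]
      s[tt$feature_b[i], tt$feature_a[i]] <- tt$rho[i]
    }
    if (min(eigen(s, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      abort(glue::glue("infeasible: correlation targets for cell type {ct} are not positive semi-definite"))
    }
    s
  })

  set.seed(seed)
  genome_length <- n_genes * gene_spacing
  slot <- (seq_len(n_genes) - 1) * gene_spacing
  strand <- rep(c("+", "-"), length.out = n_genes)
  # window is [slot, slot + 13000) on either strand by TSS placement
  tss <- if_else(strand == "+", slot + 3000, slot + 10000)
  genes <- tibble(
    gene_id = sprintf("gene%04d", seq_len(n_genes)),
    chrom = "chrS", strand = strand,
    start = if_else(strand == "+", tss, tss - 2000),
    end = if_else(strand == "+", tss + 2000, tss), tss = tss)

  tracks <- list()
  for (ct in names(by_ct)) {
    f <- feat_of[[ct]]
    # eigen square root (not Cholesky) so exactly singular targets like
    # rho = 1 remain generable
    eg <- eigen(sigmas[[ct]], symmetric = TRUE)
    rt <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), length(f)) %*% t(eg$vectors)
    z <- matrix(rnorm(n_genes * length(f)), n_genes) %*% rt
    x <- pmax(mean_signal + sd_signal * z, 1)
    colnames(x) <- f
    for (j in seq_along(f)) {
      ps <- slot + 250 + (j - 1) * 1500  # feature-specific window offset
      tracks[[paste(ct, f[j], sep = ":")]] <- tibble(
        feature = f[j], cell_type = ct, chrom = "chrS",
        start = ps, end = ps + peak_width, strand = "*",
        height = x[, j] / peak_width, total_signal = x[, j],
        width = peak_width)
    }
    tt <- by_ct[[ct]]
    for (p in seq_len(nrow(tt))) {
      cs <- tt$c_star[p]
      if (cs == 0) next
      g <- sort(sample.int(n_genes, cs, replace = FALSE))
      base <- slot[g] + 13500 + (p - 1) * stripe_w
      # jitter kept positive and < stripe width - peak width so planted
      # loci of different pairs never touch
      jit <- round(runif(cs, 0, 300))
      wpk <- 400
      mk <- function(feat, st) tibble(
        feature = feat, cell_type = ct, chrom = "chrS",
        start = st, end = st + wpk, strand = "*",
        height = 1, total_signal = wpk, width = wpk)
      ka <- paste(ct, tt$feature_a[p], sep = ":")
      kb <- paste(ct, tt$feature_b[p], sep = ":")
      tracks[[ka]] <- bind_rows(tracks[[ka]], mk(tt$feature_a[p], base))
      tracks[[kb]] <- bind_rows(tracks[[kb]], mk(tt$feature_b[p], base + jit))
    }
  }
  tracks <- purrr::map(tracks, ~ arrange(.x, .data$chrom, .data$start, .data$end))
  manifest <- build_manifest(tibble(
    cell_type = rep(names(feat_of), lengths(feat_of)),
    feature = unlist(feat_of, use.names = FALSE)))

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(tracks)) {
      write_narrowpeak(tracks[[nm]], file.path(dir, paste0(gsub(":", ".", nm), ".narrowPeak")))
    }
    write_genes_bed12(genes, file.path(dir, "genes.bed12"))
    readr::write_tsv(manifest, file.path(dir, "manifest.tsv"), progress = FALSE)
  }
  list(tracks = tracks, genes = genes, manifest = manifest,
       genome_length = genome_length, pair_targets = pair_targets)
}

#' Simulate a hockey-stick enhancer landscape with known super-enhancers
#'
#' Generates an H3K27ac-like peak track whose total-signal distribution is
#' heavy-tailed with a planted super/typical split: `n_typical` peaks with
#' lognormal widths and ~1 unit/bp signal density, plus `n_super` much
#' wider peaks whose signal density is `signal_ratio`-fold higher, shuffled
#' over well-separated slots (gap > any stitch distance, so stitching is
#' the identity and the ground-truth labels carry over). Optionally plants
#' a CTCF track whose peaks preferentially sit inside the widest enhancer
#' peaks, with lognormal peak heights.
#'
#' @param n_typical,n_super Peak counts (`n_super >= 1`).
#' @param signal_ratio Signal-density fold change of supers over typicals;
#'   `<= 1` leaves no reliable inflection (warned).
#' @param seed Integer seed.
#' @param ctcf `"none"` or `"width-biased"`.
#' @param spacing Slot size in bp (default 30000, larger than the default
#'   stitch distance).
#' @return List: `enhancers` (peak track with logical `true_super`),
#'   `ctcf` (peak track or `NULL`).
#' @export
simulate_enhancer_landscape <- function(n_typical = 990, n_super = 10,
                                        signal_ratio = 50, seed = 1,
                                        ctcf = c("none", "width-biased"),
                                        spacing = 30000) {
  ctcf <- match.arg(ctcf)
  stopifnot(n_super >= 1, n_typical >= 1)
  if (signal_ratio <= 1) {
    warn("signal_ratio <= 1: super and typical enhancers are not separable, no reliable inflection")
  }
  set.seed(seed)
  n <- n_typical + n_super
  is_super <- rep(c(FALSE, TRUE), c(n_typical, n_super))[sample.int(n)]
  width <- ifelse(is_super,
                  round(stats::rlnorm(n, log(9000), 0.25)),
                  round(stats::rlnorm(n, log(900), 0.45)))
  width <- pmin(width, spacing - 14000)
  density <- stats::rgamma(n, shape = 8, rate = 8) *
    ifelse(is_super, signal_ratio, 1)
  start <- (seq_len(n) - 1) * spacing + 500
  enh <- tibble(
    feature = "H3K27ac", cell_type = "sim", chrom = "chrS",
    start = start, end = start + width, strand = "*",
    height = density, total_signal = density * width, width = width,
    true_super = is_super)

  ctcf_track <- NULL
  if (ctcf == "width-biased") {
    pr <- (rank(width) / n)^3  # widest peaks most likely to carry CTCF
    carrier <- runif(n) < pr
    pos <- start[carrier] + round(runif(sum(carrier)) * pmax(width[carrier] - 200, 1))
    # background CTCF peaks spread uniformly over the genome
    n_bg <- n
    bg <- round(runif(n_bg, 0, n * spacing - 200))
    all_start <- c(pos, bg)
    ctcf_track <- tibble(
      feature = "CTCF", cell_type = "sim", chrom = "chrS",
      start = all_start, end = all_start + 200, strand = "*",
      height = stats::rlnorm(length(all_start), log(10), 0.6),
      width = 200) |>
      mutate(total_signal = .data$height * .data$width) |>
      arrange(.data$chrom, .data$start, .data$end)
  }
  list(enhancers = arrange(enh, .data$chrom, .data$start), ctcf = ctcf_track)
}

#' Write a peak track as ENCODE narrowPeak
#'
#' `signalValue` carries the peak height; re-reading with [read_peaks()]
#' recovers `height` exactly and `total_signal` as `height * width`.
#'
#' @param track Peak track tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(track, path) {
  check_track(track)
  np <- tibble(
    chrom = track$chrom,
    start = format(track$start, scientific = FALSE, trim = TRUE),
    end = format(track$end, scientific = FALSE, trim = TRUE),
    name = sprintf("%s_%d", track$feature, seq_len(nrow(track))),
    score = 0L,
    strand = if_else(track$strand %in% c("+", "-"), track$strand, "."),
    signalValue = format(track$height, scientific = FALSE, trim = TRUE, digits = 15),
    pValue = -1L, qValue = -1L, peak = -1L)
  readr::write_tsv(np, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write a gene model tibble as BED12
#' @param genes Gene model tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes_bed12 <- function(genes, path) {
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  bed <- tibble(
    chrom = genes$chrom, start = fmt(genes$start), end = fmt(genes$end),
    name = genes$gene_id, score = 0L, strand = genes$strand,
    thickStart = fmt(genes$start), thickEnd = fmt(genes$end), rgb = "0",
    blockCount = 1L, blockSizes = fmt(genes$end - genes$start),
    blockStarts = "0")
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
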