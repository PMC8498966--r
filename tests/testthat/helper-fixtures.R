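# fixtures built in code; no data files

# random peak track on a toy genome (non-degenerate signals)
random_track <- function(n, seed, chroms = c("chr1", "chr2"), max_pos = 5000,
                         max_width = 120, feature = "f", cell_type = "toy") {
  set.seed(seed)
  start <- sample.int(max_pos, n, replace = TRUE)
  width <- sample.int(max_width, n, replace = TRUE)
  toy_track(
    tibble::tibble(
      chrom = sample(chroms, n, replace = TRUE),
      start = start, end = start + width,
      height = stats::runif(n, 0.5, 10),
      total_signal = stats::runif(n, 10, 500)),
    feature = feature, cell_type = cell_type)
}

# O(n^2) all-pairs colocalization oracle
brute_force_coloc <- function(a, b) {
  n <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (intervals_overlap(a$chrom[i], a$start[i], a$end[i],
                            b$chrom[j], b$start[j], b$end[j])) n <- n + 1L
    }
  }
  n
}

# exhaustive tangent-slope search over the ascending scaled rank-signal
# curve: first point whose forward slope reaches 1
brute_force_se_cutoff <- function(signal) {
  s <- sort(signal)
  n <- length(s)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- s / max(s)
  for (i in seq_len(n - 1)) {
    if ((y[i + 1] - y[i]) / (x[i + 1] - x[i]) >= 1) return(i)
  }
  NA_integer_
}

# per-gene signal tibble shorthand
sig_tbl <- function(x, w = x + 1, ids = sprintf("g%03d", seq_along(x)), feature = "f") {
  tibble::tibble(gene_id = ids, feature = feature, x = x, w = w, k = as.integer(x > 0))
}

# evenly spaced plus-strand genes on one chromosome
toy_genes <- function(n, spacing = 20000, chrom = "chr1") {
  tss <- (seq_len(n) - 1) * spacing + 4000
  tibble::tibble(gene_id = sprintf("g%03d", seq_len(n)), chrom = chrom,
                 strand = "+", start = tss, end = tss + 2000, tss = tss)
}

# background + planted-pair panel used by scoring tests: 15 background
# (A, B) pairs with graded correlation and correlation-tracking planted
# colocalization, plus one independent-signal high-colocalization pair
planted_panel_targets <- function(seed) {
  set.seed(seed + 1000L)
  rho <- seq(0.1, 0.9, length.out = 15)
  c_bg <- pmax(5L, as.integer(round(20 + 150 * rho + stats::rnorm(15, 0, 30))))
  dplyr::bind_rows(
    tibble::tibble(cell_type = sprintf("bg%02d", 1:15), feature_a = "A",
                   feature_b = "B", rho = rho, c_star = c_bg),
    tibble::tibble(cell_type = "planted", feature_a = "A", feature_b = "B",
                   rho = 0, c_star = 300L))
}

score_planted_panel <- function(seed, n_genes = 800) {
  targets <- planted_panel_targets(seed)
  pan <- simulate_panel(targets, n_genes = n_genes, seed = seed)
  suppressWarnings(
    score_panel(pan$manifest, pan$tracks, pan$genes,
                joint_mode = "empirical", bins = 8))
}
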