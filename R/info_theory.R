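#' Poisson probability of an observed promoter signal
#'
#' Probability mass of observing signal `x` in a promoter under a Poisson
#' background with rate `lam`. Signals are continuous ChIP-seq totals, so
#' `x` is rounded to the nearest integer count before evaluation; the pmf is
#' computed in log space so large signals do not underflow prematurely.
#'
#' @param x Observed signal(s), >= 0.
#' @param lam Poisson rate(s), >= 0 (recycled).
#' @param log Return the log pmf instead.
#' @return Probability in `(0, 1]` (`poisson_prob(0, 0)` is 1 by the
#'   degenerate-Poisson convention).
#' @examples
#' poisson_prob(2, 1)  # exp(-1)/2
#' @export
poisson_prob <- function(x, lam, log = FALSE) {
  if (any(x < 0) || any(lam < 0)) abort("poisson_prob: x and lam must be >= 0")
  lp <- dpois(round(x), lam, log = TRUE)
  if (log) lp else exp(lp)
}

#' Per-gene Poisson background rates for a peak track
#'
#' Two estimation modes for the rate of signal expected in each gene's
#' promoter window under the null of no enrichment:
#' * `"global"`: a uniform background, track-wide total signal divided by
#'   the effective genome length, times the gene's window width;
#' * `"promoter-mean"`: the mean observed promoter signal across genes,
#'   identical for every gene.
#'
#' @param signals Per-gene signal tibble from [map_peaks_to_promoters()].
#' @param mode `"global"` or `"promoter-mean"`.
#' @param track_total_signal Track-wide summed signal (global mode).
#' @param genome_length Effective genome length in bp (global mode).
#' @param window_width Promoter window width(s) in bp (global mode;
#'   default 13000).
#' @return Numeric vector of rates, one per gene (aligned to `signals`).
#' @export
poisson_rates <- function(signals, mode = c("global", "promoter-mean"),
                          track_total_signal = NULL, genome_length = NULL,
                          window_width = 13000) {
  mode <- match.arg(mode)
  if (mode == "promoter-mean") {
    rep(mean(signals$x), nrow(signals))
  } else {
    if (is.null(track_total_signal) || is.null(genome_length)) {
      abort("global lambda mode needs track_total_signal and genome_length")
    }
    rep_len(track_total_signal / genome_length * window_width, nrow(signals))
  }
}

#' Entropy of per-gene promoter signals under a Poisson model
#'
#' Computes `H = -sum_i p_i log p_i` over genes, where
#' `p_i = poisson_prob(x_i, lambda_i)` is the Poisson probability of gene
#' i's observed promoter signal. Note this sums over genes, not over
#' distinct signal values: duplicating every gene doubles H. Each term
#' `-p log p >= 0` since `p` is in `(0, 1]`, so `H >= 0`; terms with
#' `p = 1` contribute 0. Evaluated as `exp(log p) * (-log p)` to avoid
#' `0 * Inf`.
#'
#' @param signals Per-gene signal tibble (column `x`).
#' @param lambda Poisson rate(s), recycled over genes.
#' @param base Logarithm base (default natural).
#' @return Scalar entropy, >= 0.
#' @export
signal_entropy <- function(signals, lambda, base = exp(1)) {
  lp <- poisson_prob(signals$x, rep_len(lambda, nrow(signals)), log = TRUE)
  sum(-exp(lp) * lp) / log(base)
}

#' Joint entropy of two per-gene signal vectors
#'
#' Two estimators:
#' * `"product-poisson"` (default): per-gene joint probability
#'   `P(x_i, y_i) = p(x_i) * p(y_i)` from the two marginal Poisson models,
#'   summed as `-sum_i P log P` over genes — the direct per-gene reading of
#'   the joint-entropy formula.
#' * `"empirical"`: plug-in histogram estimator on `bins x bins`
#'   equal-occupancy bins of `(x, y)` across genes, `-sum_b f_b log f_b`
#'   over occupied joint bins.
#'
#' @param sig_a,sig_b Per-gene signal tibbles over the same gene universe.
#' @param lambda_a,lambda_b Poisson rates (product-poisson mode).
#' @param joint_mode `"product-poisson"` or `"empirical"`.
#' @param bins Equal-occupancy bins per margin (empirical mode).
#' @param base Logarithm base.
#' @return Scalar joint entropy.
#' @export
joint_entropy <- function(sig_a, sig_b, lambda_a = NULL, lambda_b = NULL,
                          joint_mode = c("product-poisson", "empirical"),
                          bins = 16, base = exp(1)) {
  joint_mode <- match.arg(joint_mode)
  align_genes(sig_a, sig_b)
  if (joint_mode == "product-poisson") {
    lp <- poisson_prob(sig_a$x, rep_len(lambda_a, nrow(sig_a)), log = TRUE) +
      poisson_prob(sig_b$x, rep_len(lambda_b, nrow(sig_b)), log = TRUE)
    sum(-exp(lp) * lp) / log(base)
  } else {
    ba <- bin_equal_occupancy(sig_a$x, bins)
    bb <- bin_equal_occupancy(sig_b$x, bins)
    f <- as.vector(table(ba, bb)) / length(ba)
    f <- f[f > 0]
    sum(-f * log(f)) / log(base)
  }
}

#' Mutual information of two features' promoter signals
#'
#' `I = H(X) + H(Y) - H(X, Y)` over per-gene promoter signals. In
#' `"product-poisson"` mode the entropies are the per-gene Poisson sums of
#' [signal_entropy()] and [joint_entropy()]; in `"empirical"` mode all
#' three entropies are plug-in histogram estimates on equal-occupancy bins,
#' so `I` is the standard binned mutual-information estimate (near 0 for
#' independent signals, equal to the marginal entropy for identical ones).
#'
#' Tracks read from plain BED carry width-valued signals; mutual
#' information over such degenerate signals is refused unless
#' `allow_degenerate_signal = TRUE`.
#'
#' @inheritParams joint_entropy
#' @param feature_a,feature_b Labels for the output row (default taken from
#'   the signal tibbles).
#' @param allow_degenerate_signal Permit width-valued fallback signals.
#' @return One-row tibble: `feature_a`, `feature_b`, `H_a`, `H_b`, `H_ab`,
#'   `I`, `joint_mode`, `log_base`. `I = H_a + H_b - H_ab` exactly and is
#'   symmetric in its arguments.
#' @export
mutual_information <- function(sig_a, sig_b, lambda_a = NULL, lambda_b = NULL,
                               joint_mode = c("product-poisson", "empirical"),
                               bins = 16, base = exp(1),
                               feature_a = NULL, feature_b = NULL,
                               allow_degenerate_signal = FALSE) {
  joint_mode <- match.arg(joint_mode)
  align_genes(sig_a, sig_b)
  if (!allow_degenerate_signal) {
    for (s in list(sig_a, sig_b)) {
      if (all(s$x == s$w) && any(s$x > 0)) {
        abort(paste("signals equal promoter widths (plain-BED fallback);",
                    "set allow_degenerate_signal = TRUE to compute MI anyway"))
      }
    }
  }
  if (joint_mode == "product-poisson") {
    h_a <- signal_entropy(sig_a, lambda_a, base)
    h_b <- signal_entropy(sig_b, lambda_b, base)
  } else {
    h_a <- binned_entropy(sig_a$x, bins, base)
    h_b <- binned_entropy(sig_b$x, bins, base)
  }
  h_ab <- joint_entropy(sig_a, sig_b, lambda_a, lambda_b, joint_mode, bins, base)
  tibble(
    feature_a = feature_a %||% sig_a$feature[1] %||% "a",
    feature_b = feature_b %||% sig_b$feature[1] %||% "b",
    H_a = h_a, H_b = h_b, H_ab = h_ab, I = h_a + h_b - h_ab,
    joint_mode = joint_mode, log_base = base
  )
}

#' Absolute Pearson correlation of two per-gene signal vectors
#'
#' The linear-correlation alternative to mutual information as the
#' association measure: `|r|` of the per-gene signals, in `[0, 1]`. Zero
#' variance in either vector yields 0 with a warning.
#'
#' @param sig_a,sig_b Per-gene signal tibbles over the same gene universe.
#' @return Scalar `|r|`.
#' @export
abs_pearson <- function(sig_a, sig_b) {
  align_genes(sig_a, sig_b)
  if (nrow(sig_a) < 3) abort("abs_pearson needs at least 3 genes")
  if (sd(sig_a$x) == 0 || sd(sig_b$x) == 0) {
    warn("zero variance in a signal vector; |r| defined as 0")
    return(0)
  }
  abs(cor(sig_a$x, sig_b$x))
}

# internal: check two per-gene signal tibbles share a gene universe, in order
align_genes <- function(sig_a, sig_b) {
  if (nrow(sig_a) != nrow(sig_b) || !identical(sig_a$gene_id, sig_b$gene_id)) {
    abort("signal vectors must cover the same genes in the same order")
  }
  invisible(NULL)
}

# internal: equal-occupancy bin assignment (quantile breaks, type 7)
bin_equal_occupancy <- function(x, bins) {
  breaks <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1), type = 7))
  if (length(breaks) < 2) return(rep(1L, length(x)))
  cut(x, breaks = breaks, include.lowest = TRUE, labels = FALSE)
}

# internal: plug-in entropy of a binned margin
binned_entropy <- function(x, bins, base = exp(1)) {
  f <- tabulate(bin_equal_occupancy(x, bins))
  f <- f[f > 0] / length(x)
  sum(-f * log(f)) / log(base)
}
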