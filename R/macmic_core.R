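#' Build the pair manifest from a feature inventory
#'
#' All unordered within-cell-type feature pairs, no self-pairs, each pair
#' listed once with `feature_a < feature_b` lexicographically. Six features
#' in a cell type give 15 pairs; the same six features across 15 cell types
#' give 225.
#'
#' @param features A tibble with columns `cell_type` and `feature` (one row
#'   per feature per cell type), or a named list of character vectors
#'   (names = cell types).
#' @return Tibble `cell_type`, `feature_a`, `feature_b`, `pair_id`, sorted
#'   lexicographically.
#' @examples
#' build_manifest(list(H1 = c("H3K4me3", "H3K27me3", "CTCF")))
#' @export
build_manifest <- function(features) {
  if (is.list(features) && !is.data.frame(features)) {
    features <- tibble(cell_type = rep(names(features), lengths(features)),
                       feature = unlist(features, use.names = FALSE))
  }
  stopifnot(all(c("cell_type", "feature") %in% names(features)))
  manifest <- features |>
    distinct(.data$cell_type, .data$feature) |>
    group_by(.data$cell_type) |>
    summarise(pairs = list(if (dplyr::n() >= 2) {
      cmb <- utils::combn(sort(.data$feature), 2)
      tibble(feature_a = cmb[1, ], feature_b = cmb[2, ])
    } else tibble(feature_a = character(), feature_b = character())),
    .groups = "drop") |>
    tidyr::unnest("pairs")
  if (nrow(manifest) == 0) abort("build_manifest: need >= 2 features in at least one cell type")
  manifest |>
    mutate(pair_id = paste(.data$cell_type, .data$feature_a, .data$feature_b, sep = ":")) |>
    arrange(.data$cell_type, .data$feature_a, .data$feature_b)
}

#' Fit the panel-wide colocalization-vs-association regression
#'
#' Ordinary least squares of colocalization counts on the association
#' measure (mutual information by default) across all pairs of a panel.
#' The fitted line supplies the expected colocalization count at each
#' pair's association value.
#'
#' @param pairs Tibble with columns `I` (association value) and
#'   `C_observed` (colocalization count); >= 3 rows, `I` not constant.
#' @return A `macmic_fit` object (list with the `lm` fit, `intercept`,
#'   `slope`, `sigma`, `n_pairs`); supports [tidy()], [glance()], `predict`.
#' @export
fit_colocalization_regression <- function(pairs) {
  stopifnot(all(c("I", "C_observed") %in% names(pairs)))
  ok <- stats::complete.cases(pairs[, c("I", "C_observed")])
  pairs <- pairs[ok, ]
  if (nrow(pairs) < 3) abort("regression needs >= 3 pairs")
  if (sd(pairs$I) == 0) abort("regression needs non-constant association values")
  model <- lm(C_observed ~ I, data = pairs)
  structure(
    list(model = model,
         intercept = unname(coef(model)[1]), slope = unname(coef(model)[2]),
         sigma = summary(model)$sigma, n_pairs = nrow(pairs)),
    class = "macmic_fit")
}

#' @export
predict.macmic_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) stats::fitted(object$model)
  else predict(object$model, newdata = newdata, ...)
}

#' @export
print.macmic_fit <- function(x, ...) {
  cat(glue::glue(
    "Colocalization ~ association OLS fit: C = {signif(x$intercept, 4)} + ",
    "{signif(x$slope, 4)} * I ({x$n_pairs} pairs, residual SE {signif(x$sigma, 4)})"),
    "\n")
  invisible(x)
}

#' @rdname fit_colocalization_regression
#' @param x A `macmic_fit`.
#' @param ... Passed on.
#' @method tidy macmic_fit
#' @export
tidy.macmic_fit <- function(x, ...) {
  as_tibble(broom::tidy(x$model, ...))
}

#' @rdname fit_colocalization_regression
#' @method glance macmic_fit
#' @export
glance.macmic_fit <- function(x, ...) {
  as_tibble(broom::glance(x$model, ...))
}

#' MACMIC score: relative excess of observed over expected colocalization
#'
#' `(C_observed - C_expected) / C_expected`. Zero when observed matches the
#' regression prediction, positive when a pair colocalizes more than its
#' association predicts. A non-positive expected count leaves the score
#' undefined (`NA`) with a warning — the regression can predict <= 0 at very
#' low association values, and clamping the denominator would fabricate
#' extreme scores.
#'
#' @param c_observed,c_expected Observed and regression-expected counts
#'   (vectorised).
#' @return Numeric score vector.
#' @examples
#' macmic_score(c(100, 200, 50), 100)  # 0, 1, -0.5
#' @export
macmic_score <- function(c_observed, c_expected) {
  out <- unname((c_observed - c_expected) / c_expected)
  bad <- !is.na(c_expected) & c_expected <= 0
  if (any(bad)) {
    warn(glue::glue("{sum(bad)} pair(s) with expected colocalization <= 0; score undefined"))
    out[bad] <- NA_real_
  }
  out
}

#' Residual p-values for pairs under the panel regression
#'
#' Externally studentized residuals of the fitted pairs, referred to a t
#' distribution with `n - 3` degrees of freedom, two-sided. A low p for a
#' pair above the line flags significantly higher colocalization than the
#' association value predicts.
#'
#' @param fit A `macmic_fit`.
#' @return Tibble `residual`, `t`, `p`, `direction` (`"above"`/`"below"`/
#'   `"on"` the line), one row per fitted pair in fit order. With `n <= 3`
#'   pairs the p-values are `NA`.
#' @export
residual_pvalue <- function(fit) {
  stopifnot(inherits(fit, "macmic_fit"))
  res <- stats::residuals(fit$model)
  n <- fit$n_pairs
  if (n <= 3) {
    warn("residual p-values undefined with <= 3 pairs")
    tval <- rep(NA_real_, n); p <- rep(NA_real_, n)
  } else {
    tval <- rstudent(fit$model)
    tval[abs(res) < 1e-12] <- 0       # exact-fit points: rstudent can 0/0
    p <- 2 * pt(-abs(tval), df = n - 3)
    # deleting the lone outlier from an otherwise exact fit gives sigma 0
    p[!is.finite(tval) & abs(res) > 1e-12] <- 0
  }
  tibble(residual = unname(res), t = unname(tval), p = unname(p),
         direction = dplyr::case_when(res > 1e-12 ~ "above",
                                      res < -1e-12 ~ "below",
                                      TRUE ~ "on"))
}

#' Score a panel of feature pairs
#'
#' The full workflow for a pair manifest: per pair, aggregate each
#' feature's promoter signals, compute the association value (mutual
#' information or `|r|`) and the genome-wide colocalization count; then fit
#' one least-squares regression of counts on association across the whole
#' panel, and report each pair's expected count, MACMIC score and residual
#' p-value. Output rows are sorted by MACMIC descending (ties: observed
#' count descending, then pair id).
#'
#' @param manifest Pair manifest from [build_manifest()].
#' @param tracks List of peak track tibbles covering every
#'   (cell_type, feature) in the manifest.
#' @param genes Gene model tibble.
#' @param assoc `"mi"` or `"abs-pearson"`.
#' @param joint_mode,lambda_mode,bins,base See [mutual_information()] and
#'   [poisson_rates()].
#' @param upstream,downstream Promoter window extent in bp.
#' @param genome_length Effective genome length for the global Poisson
#'   rate; default: summed per-chromosome maximum peak end over all tracks.
#' @param coloc_mode Colocalization counting mode, see
#'   [count_colocalizations()].
#' @param allow_degenerate_signal Passed to [mutual_information()].
#' @return A `macmic_panel` object: list with `pairs` (the scored tibble),
#'   `fit` (the `macmic_fit`) and `config`. [tidy()] returns the pair
#'   table, [glance()] the fit summary, [autoplot()] the
#'   association-vs-colocalization scatter.
#' @export
score_panel <- function(manifest, tracks, genes,
                        assoc = c("mi", "abs-pearson"),
                        joint_mode = c("product-poisson", "empirical"),
                        lambda_mode = c("global", "promoter-mean"),
                        bins = 16, base = exp(1),
                        upstream = 3000, downstream = 10000,
                        genome_length = NULL,
                        coloc_mode = c("pairs", "merged-loci"),
                        allow_degenerate_signal = FALSE) {
  assoc <- match.arg(assoc); joint_mode <- match.arg(joint_mode)
  lambda_mode <- match.arg(lambda_mode); coloc_mode <- match.arg(coloc_mode)

  key <- function(ct, f) paste(ct, f, sep = ":")
  track_tbl <- purrr::map(tracks, check_track)
  names(track_tbl) <- purrr::map_chr(track_tbl, ~ key(.x$cell_type[1], .x$feature[1]))
  needed <- unique(c(key(manifest$cell_type, manifest$feature_a),
                     key(manifest$cell_type, manifest$feature_b)))
  missing_tracks <- setdiff(needed, names(track_tbl))
  if (length(missing_tracks) > 0) {
    abort(glue::glue("missing track(s) for: {toString(missing_tracks)}"))
  }
  if (is.null(genome_length)) {
    genome_length <- bind_rows(track_tbl) |>
      group_by(.data$chrom) |>
      summarise(len = max(.data$end), .groups = "drop") |>
      pull("len") |>
      sum()
  }

  signals <- purrr::map(track_tbl[needed], map_peaks_to_promoters,
                        genes = genes, upstream = upstream, downstream = downstream)
  window_w <- promoter_windows(genes, upstream, downstream)
  window_w <- window_w$window_end - window_w$window_start
  lambdas <- purrr::map(needed, function(k) {
    poisson_rates(signals[[k]], mode = lambda_mode,
                  track_total_signal = sum(track_tbl[[k]]$total_signal),
                  genome_length = genome_length, window_width = window_w)
  })
  names(lambdas) <- needed

  per_pair <- purrr::pmap(manifest, function(cell_type, feature_a, feature_b, pair_id) {
    ka <- key(cell_type, feature_a); kb <- key(cell_type, feature_b)
    tryCatch({
      i_val <- if (assoc == "mi") {
        mutual_information(signals[[ka]], signals[[kb]],
                           lambda_a = lambdas[[ka]], lambda_b = lambdas[[kb]],
                           joint_mode = joint_mode, bins = bins, base = base,
                           allow_degenerate_signal = allow_degenerate_signal)$I
      } else {
        abs_pearson(signals[[ka]], signals[[kb]])
      }
      c_obs <- count_colocalizations(track_tbl[[ka]], track_tbl[[kb]], mode = coloc_mode)
      tibble(pair_id = pair_id, cell_type = cell_type,
             feature_a = feature_a, feature_b = feature_b,
             I = i_val, C_observed = c_obs)
    }, error = function(e) {
      warn(glue::glue("pair {pair_id} failed: {conditionMessage(e)}"))
      tibble(pair_id = pair_id, cell_type = cell_type,
             feature_a = feature_a, feature_b = feature_b,
             I = NA_real_, C_observed = NA_integer_)
    })
  })
  pairs <- list_rbind(per_pair)

  fit <- fit_colocalization_regression(pairs)
  ok <- stats::complete.cases(pairs[, c("I", "C_observed")])
  resid <- residual_pvalue(fit)
  pairs$C_expected <- NA_real_
  pairs$C_expected[ok] <- predict(fit)
  pairs$macmic <- macmic_score(pairs$C_observed, pairs$C_expected)
  pairs$residual_p <- NA_real_; pairs$direction <- NA_character_
  pairs$residual_p[ok] <- resid$p
  pairs$direction[ok] <- resid$direction
  pairs <- pairs |>
    arrange(desc(.data$macmic), desc(.data$C_observed), .data$pair_id) |>
    mutate(rank = row_number())

  structure(
    list(pairs = pairs, fit = fit,
         config = list(assoc = assoc, joint_mode = joint_mode,
                       lambda_mode = lambda_mode, bins = bins, log_base = base,
                       upstream = upstream, downstream = downstream,
                       genome_length = genome_length, coloc_mode = coloc_mode)),
    class = "macmic_panel")
}

#' @export
print.macmic_panel <- function(x, ...) {
  cat(glue::glue("MACMIC panel: {nrow(x$pairs)} pairs ",
                 "(assoc = {x$config$assoc}, joint_mode = {x$config$joint_mode})"), "\n")
  print(x$fit)
  print(head(x$pairs, 5))
  invisible(x)
}

#' @rdname score_panel
#' @param x A `macmic_panel`.
#' @param ... Unused.
#' @method tidy macmic_panel
#' @export
tidy.macmic_panel <- function(x, ...) x$pairs

#' @rdname score_panel
#' @method glance macmic_panel
#' @export
glance.macmic_panel <- function(x, ...) {
  glance(x$fit) |>
    mutate(intercept = x$fit$intercept, slope = x$fit$slope,
           n_pairs = x$fit$n_pairs, assoc = x$config$assoc,
           joint_mode = x$config$joint_mode)
}

#' @rdname score_panel
#' @param object A `macmic_panel`.
#' @method autoplot macmic_panel
#' @export
autoplot.macmic_panel <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$I, y = .data$C_observed)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$macmic)) +
    ggplot2::geom_abline(intercept = object$fit$intercept, slope = object$fit$slope,
                         linetype = "dashed") +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = sprintf("association (%s)", object$config$assoc),
                  y = "colocalization count", colour = "MACMIC") +
    ggplot2::theme_minimal()
}
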