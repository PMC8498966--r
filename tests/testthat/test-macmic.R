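test_that("manifest enumerates unordered within-cell-type pairs", {
  m1 <- build_manifest(list(ct = paste0("f", 1:6)))
  expect_equal(nrow(m1), 15)
  m2 <- build_manifest(tidyr::crossing(cell_type = paste0("ct", 1:15),
                                       feature = paste0("f", 1:6)))
  expect_equal(nrow(m2), 225)
  expect_equal(nrow(build_manifest(list(ct = c("a", "b")))), 1)
  expect_false(any(m2$feature_a == m2$feature_b))
  expect_false(any(duplicated(m2$pair_id)))
  expect_error(build_manifest(list(ct = "only")), ">= 2 features")
})

test_that("OLS fit recovers exact lines and rejects degenerate designs", {
  pairs <- tibble::tibble(I = c(0.1, 0.5, 1, 2), C_observed = 2 + 3 * c(0.1, 0.5, 1, 2))
  fit <- suppressWarnings(fit_colocalization_regression(pairs))
  expect_equal(fit$intercept, 2, tolerance = 1e-10)
  expect_equal(fit$slope, 3, tolerance = 1e-10)
  expect_error(fit_colocalization_regression(
    tibble::tibble(I = rep(1, 5), C_observed = 1:5)), "non-constant")
  expect_error(fit_colocalization_regression(
    tibble::tibble(I = 1:2, C_observed = 1:2)), ">= 3")
  # duplicated points equal the weighted problem: same line either way
  dup <- suppressWarnings(fit_colocalization_regression(pairs[c(1, 1, 2, 2, 3, 3, 4, 4), ]))
  expect_equal(dup$intercept, fit$intercept, tolerance = 1e-10)
  expect_equal(dup$slope, fit$slope, tolerance = 1e-10)
})

test_that("OLS residuals sum to zero and slope is recovered within its 95% CI", {
  set.seed(2)
  I <- runif(225, 0.05, 2)
  pairs <- tibble::tibble(I = I, C_observed = 100 + 400 * I + rnorm(225, 0, 20))
  fit <- fit_colocalization_regression(pairs)
  expect_lt(abs(sum(stats::residuals(fit$model))), 1e-9)
  ci <- stats::confint(fit$model)
  expect_gte(400, ci["I", 1]); expect_lte(400, ci["I", 2])
  expect_gte(100, ci["(Intercept)", 1]); expect_lte(100, ci["(Intercept)", 2])
})

test_that("macmic_score identities hold and non-positive denominators are NA", {
  expect_equal(macmic_score(c(100, 200, 50), c(100, 100, 100)), c(0, 1, -0.5))
  expect_warning(s <- macmic_score(10, -5), "undefined")
  expect_true(is.na(s))
})

test_that("residual p is 1 on the line and small for an engineered outlier", {
  set.seed(12)
  I <- seq(0.1, 2, length.out = 20)
  C <- 10 + 5 * I + rnorm(20, 0, 0.2)
  C[20] <- C[20] + 100  # far above an otherwise near-exact line
  fit <- fit_colocalization_regression(tibble::tibble(I = I, C_observed = C))
  rp <- residual_pvalue(fit)
  expect_lt(rp$p[20], 0.05)
  expect_equal(rp$direction[20], "above")
  exact <- suppressWarnings(fit_colocalization_regression(
    tibble::tibble(I = c(0.5, 1, 1.5, 2), C_observed = 2 + 3 * c(0.5, 1, 1.5, 2))))
  rp2 <- residual_pvalue(exact)
  expect_equal(rp2$p, rep(1, 4))
  expect_equal(rp2$direction, rep("on", 4))
})

test_that("residual p-values are uniform under a simulated null", {
  set.seed(11)
  I <- runif(200, 0.05, 2)
  pairs <- tibble::tibble(I = I, C_observed = 100 + 400 * I + rnorm(200, 0, 25))
  fit <- fit_colocalization_regression(pairs)
  ks <- suppressWarnings(ks.test(residual_pvalue(fit)$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a planted high-colocalization, independent-signal pair tops the panel", {
  panel <- score_planted_panel(seed = 101)
  top <- tidy(panel)[1, ]
  expect_equal(top$cell_type, "planted")
  expect_gt(top$macmic, 0)
  expect_equal(top$direction, "above")
})

test_that("panel scoring is deterministic and scale-free on exact-fit panels", {
  p1 <- score_planted_panel(seed = 55, n_genes = 400)
  p2 <- score_planted_panel(seed = 55, n_genes = 400)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  readr::write_tsv(tidy(p1), f1, progress = FALSE)
  readr::write_tsv(tidy(p2), f2, progress = FALSE)
  expect_identical(readLines(f1), readLines(f2))
  # macmic is invariant to uniform rescaling of colocalization counts when
  # observed and expected scale together (exact-fit panel)
  I <- c(0.2, 0.6, 1.1, 1.7)
  C <- 5 + 20 * I
  for (k in c(1, 3, 10)) {
    fit <- suppressWarnings(fit_colocalization_regression(tibble::tibble(I = I, C_observed = k * C)))
    expect_equal(macmic_score(k * C, predict(fit)), rep(0, 4), tolerance = 1e-9)
  }
})

test_that("tidy, glance and autoplot expose the panel results", {
  panel <- score_planted_panel(seed = 7, n_genes = 300)
  td <- tidy(panel)
  expect_true(all(c("pair_id", "I", "C_observed", "C_expected", "macmic",
                    "residual_p", "rank") %in% names(td)))
  expect_equal(nrow(td), 16)
  gl <- glance(panel)
  expect_equal(gl$n_pairs, 16)
  expect_s3_class(autoplot(panel), "ggplot")
  expect_output(print(panel), "MACMIC panel")
})

test_that("abs-pearson association mode runs the same workflow", {
  targets <- planted_panel_targets(3)
  pan <- simulate_panel(targets, n_genes = 300, seed = 3)
  p <- suppressWarnings(score_panel(pan$manifest, pan$tracks, pan$genes,
                                    assoc = "abs-pearson"))
  expect_equal(nrow(tidy(p)), 16)
  expect_true(all(tidy(p)$I >= 0 & tidy(p)$I <= 1, na.rm = TRUE))
  expect_equal(tidy(p)$cell_type[1], "planted")
})
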