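test_that("poisson_prob matches the closed-form pmf and normalizes", {
  expect_equal(poisson_prob(0, 0), 1)
  expect_equal(poisson_prob(2, 1), exp(-1) / 2)
  expect_equal(sum(poisson_prob(0:200, 3)), 1, tolerance = 1e-9)
  expect_error(poisson_prob(-1, 2), ">= 0")
  expect_error(poisson_prob(1, -2), ">= 0")
  # continuous signals are rounded to counts before evaluation
  expect_equal(poisson_prob(2.4, 1), poisson_prob(2, 1))
})

test_that("entropy is the per-gene sum of -p log p terms", {
  expect_equal(signal_entropy(sig_tbl(c(0, 0, 0)), lambda = 0), 0)
  # three-gene oracle: hand-evaluated term by term from the pmf
  s <- sig_tbl(c(1, 2, 3))
  lam <- c(1, 2, 3)
  p <- dpois(1:3, lam)
  expect_equal(signal_entropy(s, lam), sum(-p * log(p)), tolerance = 1e-12)
  # sum over genes, not distinct values: duplication doubles H
  s2 <- sig_tbl(c(1, 2, 3, 1, 2, 3))
  expect_equal(signal_entropy(s2, rep(lam, 2)), 2 * signal_entropy(s, lam))
  expect_gte(signal_entropy(sig_tbl(round(runif(50, 0, 20))), lambda = 4), 0)
})

test_that("product-poisson joint entropy matches the term-by-term oracle", {
  set.seed(2)
  x <- round(runif(30, 0, 15)); y <- round(runif(30, 0, 15))
  sa <- sig_tbl(x); sb <- sig_tbl(y)
  la <- 4; lb <- 6
  oracle <- sum(vapply(seq_along(x), function(i) {
    pij <- dpois(x[i], la) * dpois(y[i], lb)
    -pij * log(pij)
  }, 0))
  expect_equal(joint_entropy(sa, sb, la, lb), oracle, tolerance = 1e-12)
  # identical vectors: P(x, x) = p^2
  p <- dpois(x, la)
  expect_equal(joint_entropy(sa, sa, la, la), sum(-p^2 * log(p^2)), tolerance = 1e-12)
  expect_equal(joint_entropy(sig_tbl(c(0, 0)), sig_tbl(c(0, 0)), 0, 0), 0)
})

test_that("mutual information is symmetric and I = H_a + H_b - H_ab exactly", {
  set.seed(3)
  sa <- sig_tbl(round(runif(60, 0, 30))); sb <- sig_tbl(round(runif(60, 0, 30)))
  mi_ab <- mutual_information(sa, sb, 5, 7)
  mi_ba <- mutual_information(sb, sa, 7, 5)
  expect_equal(mi_ab$I, mi_ba$I)
  expect_equal(mi_ab$I, mi_ab$H_a + mi_ab$H_b - mi_ab$H_ab)
  # jointly permuting genes leaves I unchanged
  perm <- sample.int(60)
  mi_p <- mutual_information(sa[perm, ], sb[perm, ], 5, 7)
  expect_equal(mi_p$I, mi_ab$I)
})

test_that("log base rescales every entropy by the same factor", {
  set.seed(4)
  sa <- sig_tbl(round(runif(40, 0, 20))); sb <- sig_tbl(round(runif(40, 0, 20)))
  nat <- mutual_information(sa, sb, 5, 5)
  bit <- mutual_information(sa, sb, 5, 5, base = 2)
  expect_equal(bit$H_a, nat$H_a / log(2))
  expect_equal(bit$H_ab, nat$H_ab / log(2))
  expect_equal(bit$I, nat$I / log(2))
})

test_that("empirical-binned MI is near zero for shuffled signals, maximal for identical", {
  set.seed(5)
  x <- rpois(4000, 20) + round(runif(4000, 0, 10))
  sa <- sig_tbl(x)
  sb <- sig_tbl(sample(x))  # independent shuffle
  i_obs <- mutual_information(sa, sb, joint_mode = "empirical")$I
  # permutation null oracle: the bias bound of the binned estimator
  i_null <- vapply(1:30, function(k) {
    mutual_information(sa, sig_tbl(sample(x)), joint_mode = "empirical")$I
  }, 0)
  expect_lte(i_obs, max(i_null) + 3 * sd(i_null))
  expect_lt(i_obs, 0.1)
  ident <- mutual_information(sa, sa, joint_mode = "empirical")
  expect_equal(ident$I, ident$H_a, tolerance = 1e-12)
})

test_that("abs_pearson handles sign, degenerate variance, and known rho", {
  sa <- sig_tbl(c(1, 5, 9, 2, 7))
  expect_equal(abs_pearson(sa, sig_tbl(2 * sa$x + 1)), 1)
  expect_equal(abs_pearson(sa, sig_tbl(-sa$x)), 1)
  expect_warning(r0 <- abs_pearson(sa, sig_tbl(rep(3, 5))), "variance")
  expect_equal(r0, 0)
  set.seed(6)
  n <- 10000
  z1 <- rnorm(n); z2 <- 0.5 * z1 + sqrt(1 - 0.25) * rnorm(n)
  expect_equal(abs_pearson(sig_tbl(z1 + 10), sig_tbl(z2 + 10)), 0.5,
               tolerance = 0.03)
})

test_that("gene-universe mismatches and degenerate signals are refused", {
  sa <- sig_tbl(c(1, 2, 3))
  sb <- sig_tbl(c(1, 2, 3), ids = c("gx", "gy", "gz"))
  expect_error(mutual_information(sa, sb, 1, 1), "same genes")
  # width-valued fallback signals: x == w everywhere
  deg <- sig_tbl(c(10, 20, 30), w = c(10, 20, 30))
  ok <- sig_tbl(c(5, 6, 7), w = c(50, 60, 70))
  expect_error(mutual_information(deg, ok, 1, 1), "degenerate")
  expect_silent(mutual_information(deg, ok, 1, 1, allow_degenerate_signal = TRUE))
})

test_that("poisson_rates supports global-background and promoter-mean modes", {
  s <- sig_tbl(c(10, 20, 30))
  expect_equal(poisson_rates(s, "promoter-mean"), rep(20, 3))
  lam <- poisson_rates(s, "global", track_total_signal = 1.3e6,
                       genome_length = 1e8, window_width = 13000)
  expect_equal(lam, rep(1.3e6 / 1e8 * 13000, 3))
})
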