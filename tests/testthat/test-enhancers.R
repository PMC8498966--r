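test_that("high-confidence threshold is the type-7 upper quartile, strictly exceeded", {
  tr <- toy_track(tibble::tibble(chrom = "chr1", start = 0:7 * 1000,
                                 end = 0:7 * 1000 + 100, height = 1:8))
  hc <- high_confidence_peaks(tr)
  expect_equal(attr(hc, "hc_threshold"), 6.25)
  expect_setequal(hc$height, c(7, 8))
  flat <- toy_track(tibble::tibble(chrom = "chr1", start = 0:5 * 1000,
                                   end = 0:5 * 1000 + 100, height = rep(4, 6)))
  expect_warning(hc2 <- high_confidence_peaks(flat), "upper quartile")
  expect_equal(nrow(hc2), 0)
  single <- toy_track(tibble::tibble(chrom = "chr1", start = 0, end = 100, height = 9))
  expect_warning(expect_warning(hc3 <- high_confidence_peaks(single)))
  expect_equal(nrow(hc3), 0)
})

test_that("stitching merges peaks within the stitch distance and is idempotent", {
  tr <- toy_track(tibble::tibble(chrom = "chr1",
                                 start = c(0, 5200, 40000),
                                 end = c(200, 5400, 40500),
                                 total_signal = c(10, 20, 5), height = 1))
  st <- stitch_peaks(tr, 12500)
  expect_equal(nrow(st), 2)  # first two are 5 kb apart
  expect_equal(st$total_signal, c(30, 5))
  st_again <- stitch_peaks(toy_track(st |> dplyr::mutate(height = 1)), 12500)
  expect_equal(st_again$start, st$start)
  expect_equal(st_again$end, st$end)
})

test_that("super-enhancer cutoff equals the exhaustive tangent-slope search", {
  sim <- simulate_enhancer_landscape(n_typical = 990, n_super = 10,
                                     signal_ratio = 50, seed = 21)
  calls <- call_superenhancers(sim$enhancers)
  expect_identical(attr(calls, "se_cutoff_index"),
                   brute_force_se_cutoff(calls$total_signal))
  # ground-truth recovery on the hockey stick
  truth <- sim$enhancers[order(sim$enhancers$start), ]
  called <- calls[order(calls$start), ]
  recall <- sum(called$is_super & truth$true_super) / sum(truth$true_super)
  expect_gte(recall, 0.9)
})

test_that("a single extreme peak is called super; tiny inputs are not", {
  base <- tibble::tibble(chrom = "chr1", start = (0:19) * 50000,
                         end = (0:19) * 50000 + 1000,
                         total_signal = c(rep(10, 19), 5000), height = 1)
  calls <- call_superenhancers(toy_track(base))
  expect_true(calls$is_super[which.max(calls$total_signal)])
  expect_equal(sum(calls$is_super), 1)
  tiny <- toy_track(tibble::tibble(chrom = "chr1", start = c(0, 50000),
                                   end = c(100, 50100), total_signal = c(1, 2),
                                   height = 1))
  expect_warning(c2 <- call_superenhancers(tiny), "fewer than 3")
  expect_false(any(c2$is_super))
})

test_that("CSE and OSE partition the super-enhancers by high-confidence CTCF", {
  enh <- tibble::tibble(chrom = "chr1",
                        start = c(0, 100000, 200000), end = c(10000, 110000, 210000),
                        width = 10000, total_signal = c(500, 400, 5),
                        n_peaks = 1L, signal_rank = c(3L, 2L, 1L),
                        is_super = c(TRUE, TRUE, FALSE))
  ctcf <- toy_track(tibble::tibble(
    chrom = "chr1", start = c(5000, 105000, 205000, 300000, 301000, 302000, 303000),
    end = c(5200, 105200, 205200, 300200, 301200, 302200, 303200),
    height = c(10, 2, 10, 1, 1, 1, 1)), feature = "CTCF")
  hc <- high_confidence_peaks(ctcf)  # Q3 = 6: keeps only the height-10 peaks
  cls <- classify_cse_ose(enh, hc)
  expect_equal(cls$ctcf_class, c("CSE", "OSE", "not-super"))
  sup <- cls[cls$is_super, ]
  expect_setequal(sup$ctcf_class, c("CSE", "OSE"))
  expect_equal(sum(sup$ctcf_class == "CSE") + sum(sup$ctcf_class == "OSE"), nrow(sup))
})

test_that("enhancer genes need 1 bp of gene-body overlap; CSE takes precedence", {
  enh <- tibble::tibble(chrom = "chr1", start = c(0, 30000), end = c(10000, 40000),
                        width = 10000, total_signal = c(100, 200),
                        is_super = TRUE, n_hc_ctcf = c(1L, 0L),
                        ctcf_class = c("CSE", "OSE"))
  genes <- tibble::tibble(
    gene_id = c("touch", "far", "both"), chrom = "chr1", strand = "+",
    start = c(9999, 10500, 9000), end = c(12000, 12500, 31000),
    tss = c(9999, 10500, 9000))
  expect_equal(assign_enhancer_genes(enh, genes, "CSE")$gene_id,
               c("both", "touch"))
  expect_message(ose <- assign_enhancer_genes(enh, genes, "OSE"), "CSE")
  expect_false("both" %in% ose$gene_id)
})

test_that("enlarged typical enhancers keep midpoints and match SE widths exactly", {
  te <- tibble::tibble(chrom = "chr1", start = c(45000, 100), end = c(45200, 300))
  se <- tibble::tibble(chrom = "chr1", start = 0, end = 10000)
  res <- enlarge_typical_enhancers(te, se, seed = 4)
  expect_equal(res$enlarged$start[1], 40100)
  expect_equal(res$enlarged$end[1], 50100)
  expect_equal(res$enlarged$width, res$enlarged$matched_width)
  # second enhancer is clipped at 0: width still exact
  expect_equal(res$enlarged$start[2], 0)
  expect_equal(res$enlarged$end[2], 10000)
  r2 <- enlarge_typical_enhancers(te, se, seed = 4)
  expect_identical(res$enlarged, r2$enlarged)
})

test_that("CTCF association is monotone in width groups on biased fixtures", {
  sim <- simulate_enhancer_landscape(n_typical = 900, n_super = 100,
                                     signal_ratio = 40, seed = 31,
                                     ctcf = "width-biased")
  grp <- width_rank_groups(sim$enhancers, group_size = 200)
  grp$has_ctcf <- GenomicRanges::countOverlaps(
    macmic:::as_granges(grp), macmic:::as_granges(sim$ctcf), minoverlap = 1L) > 0
  frac <- tapply(grp$has_ctcf, grp$group, mean)
  rho <- suppressWarnings(cor(seq_along(frac), as.vector(frac), method = "spearman"))
  expect_lt(rho, 0)
})

test_that("enlargement raises typical-enhancer CTCF association toward the super rate", {
  hits <- 0
  for (seed in 1:20) {
    sim <- simulate_enhancer_landscape(n_typical = 300, n_super = 30,
                                       signal_ratio = 40, seed = seed,
                                       ctcf = "width-biased")
    calls <- call_superenhancers(sim$enhancers)
    res <- enlarge_typical_enhancers(calls[!calls$is_super, ],
                                     calls[calls$is_super, ],
                                     ctcf = sim$ctcf, seed = seed)
    a <- res$association
    ok <- a$ctcf_fraction[a$collection == "enlarged_typical"] >
      a$ctcf_fraction[a$collection == "typical"] &&
      a$ctcf_fraction[a$collection == "enlarged_typical"] <
        a$ctcf_fraction[a$collection == "super"]
    hits <- hits + ok
  }
  expect_gte(hits, 18)  # allow rare sampling flukes across seeds
})
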