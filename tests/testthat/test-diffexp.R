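two_group_design <- function(n_ref, n_mut) {
  tibble::tibble(
    sample_id = c(paste0("r", seq_len(n_ref)), paste0("m", seq_len(n_mut))),
    genotype = c(rep("ref", n_ref), rep("G", n_mut)),
    timepoint = "2h",
    replicate = c(seq_len(n_ref), seq_len(n_mut)),
    library_size = 1e6)
}

test_that("median-of-ratios size factors match hand computations", {
  cm <- tibble::tibble(gene_id = c("a", "b", "c"),
                       s1 = c(10L, 20L, 30L), s2 = c(10L, 20L, 30L))
  expect_equal(unname(size_factors(cm)), c(1, 1))
  cm2 <- tibble::tibble(gene_id = c("a", "b", "c"),
                        s1 = c(10L, 20L, 30L), s2 = c(20L, 40L, 60L))
  expect_equal(unname(size_factors(cm2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  # genes with a zero anywhere are excluded and do not move the factors
  cm3 <- dplyr::bind_rows(cm2, tibble::tibble(gene_id = "z", s1 = 0L,
                                              s2 = 1000L))
  expect_equal(size_factors(cm3), size_factors(cm2))
  expect_error(size_factors(tibble::tibble(gene_id = c("a", "b"),
                                           s1 = c(0L, 5L),
                                           s2 = c(5L, 0L))), "nonzero")
})

test_that("the NB Wald test respects null identity and the log2FC formula", {
  d <- two_group_design(2, 2)
  cm <- tibble::tibble(gene_id = c("id", "fc", "zz"),
                       r1 = c(10L, 100L, 0L), r2 = c(10L, 100L, 0L),
                       m1 = c(10L, 50L, 0L), m2 = c(10L, 50L, 0L))
  sf <- setNames(rep(1, 4), d$sample_id)
  res <- nb_test(cm, d, "G", "2h", sf = sf)
  expect_equal(res$log2FC[1], 0)
  expect_equal(res$p[1], 1)
  expect_equal(res$log2FC[2], log2(50.5 / 100.5), tolerance = 1e-12)
  # zero counts in both groups: ns with p = 1
  expect_equal(res$p[3], 1)
  expect_equal(res$log2FC[3], 0)
})

test_that("swapping the groups flips log2FC and preserves p", {
  withr::with_seed(42, {
    n <- 50
    a <- matrix(rnbinom(n * 2, size = 20, mu = 100), n, 2)
    b <- matrix(rnbinom(n * 2, size = 20, mu = 60), n, 2)
  })
  d <- two_group_design(2, 2)
  sf <- setNames(rep(1, 4), d$sample_id)
  fwd <- tibble::tibble(gene_id = sprintf("g%02d", 1:50),
                        r1 = a[, 1], r2 = a[, 2], m1 = b[, 1], m2 = b[, 2])
  rev <- tibble::tibble(gene_id = sprintf("g%02d", 1:50),
                        r1 = b[, 1], r2 = b[, 2], m1 = a[, 1], m2 = a[, 2])
  res_f <- nb_test(fwd, d, "G", "2h", sf = sf)
  res_r <- nb_test(rev, d, "G", "2h", sf = sf)
  expect_equal(res_f$log2FC, -res_r$log2FC, tolerance = 1e-12)
  expect_equal(res_f$p, res_r$p, tolerance = 1e-12)
})

test_that("BH adjustment and call thresholds follow the published rules", {
  base <- tibble::tibble(gene_id = c("a", "b", "c"), genotype = "G",
                         timepoint = "2h", baseMean_ref = 100,
                         baseMean_mut = 10, log2FC = -3, dispersion = 0.1,
                         wald_z = -5, p = c(0.01, 0.02, 0.03))
  out <- adjust_and_call(base)
  # BH step-up by hand: (0.03, 0.03, 0.03)
  expect_equal(out$padj, rep(0.03, 3))
  expect_true(all(out$padj >= out$p))
  expect_true(all(out$padj <= 1))
  # monotone in p
  expect_false(is.unsorted(out$padj[order(out$p)]))

  thr <- tibble::tibble(gene_id = c("at", "below", "alpha_edge"),
                        genotype = "G", timepoint = "2h",
                        baseMean_ref = 100, baseMean_mut = 10,
                        log2FC = c(-log2(1.5), -log2(1.5001), -log2(3)),
                        dispersion = 0.1, wald_z = -5,
                        p = c(1e-6, 1e-6, 0.05))
  res <- adjust_and_call(thr)
  # fold change exactly 1.5 is not called
  expect_equal(res$call[1], "ns")
  expect_equal(res$call[2], "down")
  # padj exactly 0.05 with a 3-fold drop is called (inclusive alpha);
  # BH keeps the largest p at 0.05 here
  expect_equal(res$padj[3], 0.05)
  expect_equal(res$call[3], "down")
})

test_that("strong effects are detected and direction is symmetric", {
  m <- build_model(60, class_mix = c(none = 0.5, single = 0.5),
                   seed = 5)
  d <- build_design(timepoints = "2h")
  cm <- simulate_counts(m, d, seed = 6)
  de <- de_all_contrasts(cm, d)
  truth <- setNames(m$dependency, m$gene_id)
  g_dep <- m$gene_id[truth == "G" & is.na(m$is_tf_gene)]
  calls_g <- dplyr::filter(de, genotype == "G", gene_id %in% g_dep)
  expect_gt(mean(calls_g$call == "down"), 0.9)
  # unrelated single mutant: not called down
  calls_a <- dplyr::filter(de, genotype == "A", gene_id %in% g_dep)
  expect_lt(mean(calls_a$call == "down"), 0.1)
})
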