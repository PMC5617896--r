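test_that("class counts are the rounded proportions and models are valid", {
  m <- build_model(100, class_mix = c(none = 0.5, single = 0.3,
                                      and = 0.1, or = 0.1),
                   seed = 1, tf_genes = FALSE)
  expect_equal(as.integer(table(m$class)[c("none", "single", "and", "or")]),
               c(50L, 30L, 10L, 10L))
  expect_true(all(m$length_bp > 0))
  expect_true(all(unlist(m$clause_effects) >= 0))
  expect_error(build_model(10, class_mix = c(none = 0.5, single = 0.4)),
               "sum to 1")
  expect_error(build_model(10, effect_range = c(-1, 2)), "effect_range")
})

test_that("identical seeds give byte-identical models and count matrices", {
  m1 <- build_model(40, seed = 11)
  m2 <- build_model(40, seed = 11)
  expect_identical(serialize(m1, NULL), serialize(m2, NULL))
  d <- build_design()
  c1 <- simulate_counts(m1, d, seed = 12)
  c2 <- simulate_counts(m2, d, seed = 12)
  expect_identical(c1, c2)
  # exactly one gene flagged per TF
  expect_equal(sort(m1$is_tf_gene[!is.na(m1$is_tf_gene)]), c("A", "G", "R"))
})

test_that("sampled dependencies are monotone (upward-closed true sets)", {
  m <- build_model(120, seed = 13, tf_genes = FALSE)
  muts <- oracle_mutant_sets()
  for (i in which(m$dependency != "none")) {
    for (a in seq_along(muts)) {
      for (b in seq_along(muts)) {
        if (all(muts[[a]] %in% muts[[b]]) &&
            eval_dnf(m$dependency[i], muts[[a]])) {
          expect_true(eval_dnf(m$dependency[i], muts[[b]]))
        }
      }
    }
  }
  # AND genes specifically: singles unsatisfied, their union satisfied
  and_genes <- which(m$class == "and")
  expect_gt(length(and_genes), 0)
  for (i in and_genes) {
    cl <- m$clauses[[i]][[1]]
    if (length(cl) == 2) {
      expect_false(eval_dnf(m$dependency[i], cl[1]))
      expect_true(eval_dnf(m$dependency[i], cl))
    }
  }
})

test_that("count means follow the regulatory logic", {
  # gene with dependency G and effect 2: deletion mean = reference / 4
  m <- build_model(4, class_mix = c(single = 1), effect_range = c(2, 2),
                   dispersion = 0, seed = 21, tf_genes = FALSE)
  g_idx <- which(m$dependency == "G")[1]
  expect_false(is.na(g_idx))
  design <- tibble::tibble(
    sample_id = c(sprintf("ref_r%d", 1:3), sprintf("G_r%d", 1:3)),
    genotype = rep(c("ref", "G"), each = 3), timepoint = "2h",
    replicate = rep(1:3, 2), library_size = 1e6)
  mu <- facreg:::model_means(m, design, depth = rep(1, 6))
  expect_equal(mu[g_idx, 4] / mu[g_idx, 1], 1 / 4, tolerance = 1e-12)

  # Poisson limit: 10,000 replicates, dispersion 0, mean within 1%
  m1 <- m[g_idx, ]
  class(m1) <- class(m)
  big <- tibble::tibble(sample_id = sprintf("ref_r%d", 1:10000),
                        genotype = "ref", timepoint = "2h",
                        replicate = 1:10000, library_size = 1e6)
  cm <- simulate_counts(m1, big, seed = 22, lib_variation = c(1, 1))
  emp <- mean(as.numeric(cm[1, -1]))
  expect_lt(abs(emp / 2^m1$baseline_log2 - 1), 0.01)
})

test_that("TF genes are hard zero in every genotype deleting them", {
  m <- build_model(10, seed = 31)
  d <- build_design()
  cm <- simulate_counts(m, d, seed = 32)
  for (tf in c(G = "gaaR", A = "araR", R = "rhaR")) {
    letter <- names(which(c(G = "gaaR", A = "araR", R = "rhaR") == tf))
    del_samples <- d$sample_id[vapply(d$genotype, function(g) {
      letter %in% facreg:::genotype_deleted(g)
    }, logical(1))]
    expect_true(all(cm[cm$gene_id == tf, del_samples] == 0))
    other <- setdiff(d$sample_id, del_samples)
    expect_true(all(cm[cm$gene_id == tf, other] > 0))
  }
})

test_that("planted motifs are recoverable at their recorded positions", {
  m <- build_model(30, seed = 41)
  pr <- generate_promoters(m, seed = 42)
  expect_equal(nchar(pr$promoters$sequence[1]), 1000)
  # every gene mentioning TF X carries >= 1 instance of X's motif
  for (i in seq_len(nrow(m))) {
    if (m$dependency[i] %in% c("none", "complex")) next
    tfs <- unique(unlist(m$clauses[[i]]))
    planted <- pr$truth$motif_id[pr$truth$gene_id == m$gene_id[i]]
    expect_true(all(tfs %in% planted))
  }
  # exact scanning recalls every truth-table instance (recall = 1)
  pats <- tf_motif_patterns()
  for (tf in unique(pr$truth$motif_id)) {
    hits <- scan_iupac(pr$promoters, parse_iupac(pats[[tf]], motif_id = tf))
    tt <- pr$truth[pr$truth$motif_id == tf, ]
    found <- paste(hits$seq_id, hits$strand, hits$start)
    expect_true(all(paste(tt$gene_id, tt$strand, tt$start) %in% found))
    # positions follow the upstream convention
    expect_equal(tt$upstream_position, 1000 - tt$start + 1)
  }
  # planting error when the promoter cannot hold the motifs
  expect_error(generate_promoters(m, promoter_len = 5), "promoter_len")
})

test_that("background match frequency agrees with the product formula", {
  # TG[CAG][GTA]GGG on uniform background: per-position per-strand
  # match probability (1/4)^5 * (3/4)^2 = 5.493e-4
  seqs <- random_dna(400, 1000, seed = 51)
  hits <- scan_iupac(seqs, "TG[CAG][GTA]GGG", strands = "+")
  n_windows <- 400 * (1000 - 7 + 1)
  p_hat <- nrow(hits) / n_windows
  p_exp <- (1 / 4)^5 * (3 / 4)^2
  expect_lt(abs(p_hat - p_exp) / p_exp, 0.25)
})
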