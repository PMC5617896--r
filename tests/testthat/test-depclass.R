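make_calls <- function(down_in, timepoint = "2h", direction = "down",
                       genes = "g1") {
  tidyr::expand_grid(gene_id = genes,
                     genotype = genotype_labels(include_reference = FALSE),
                     timepoint = timepoint) |>
    dplyr::mutate(call = ifelse(.data$genotype %in% down_in, direction, "ns"),
                  log2FC = ifelse(.data$call == direction,
                                  ifelse(direction == "down", -2, 2), 0))
}

test_that("down_pattern extracts bits in the fixed genotype order", {
  calls <- make_calls(c("G", "AG", "GR", "AGR"))
  pat <- down_pattern(calls, "2h", "down")
  expect_equal(unlist(pat[1, c("G", "A", "R", "AG", "AR", "GR", "AGR")]),
               c(G = TRUE, A = FALSE, R = FALSE, AG = TRUE, AR = FALSE,
                 GR = TRUE, AGR = TRUE))
  # up-direction calls give the same bits for direction = "up"
  up_calls <- make_calls(c("G", "AG", "GR", "AGR"), direction = "up")
  pat_up <- down_pattern(up_calls, "2h", "up")
  expect_equal(unlist(pat_up[1, genotype_labels(FALSE)]),
               unlist(pat[1, genotype_labels(FALSE)]))
  # all-ns gives the all-false pattern
  none <- down_pattern(make_calls(character(0)), "2h", "down")
  expect_false(any(unlist(none[1, genotype_labels(FALSE)])))
  expect_error(down_pattern(dplyr::filter(calls, genotype != "AR"),
                            "2h", "down"), "AR")
})

test_that("the narrative regulation patterns classify as published", {
  cases <- list(
    list(down = c("G", "AG", "GR", "AGR"), expr = "G", class = "single"),
    list(down = c("AG", "AGR"), expr = "G&A", class = "and"),
    list(down = c("AG", "GR", "AGR"), expr = "(G&A)|(G&R)", class = "mixed"),
    list(down = c("G", "A", "AG", "AR", "GR", "AGR"), expr = "G|A",
         class = "or"),
    list(down = "G", expr = "complex", class = "complex")
  )
  for (cs in cases) {
    res <- infer_dependency(down_pattern(make_calls(cs$down), "2h", "down"))
    expect_equal(res$expression, cs$expr)
    expect_equal(res$class, cs$class)
  }
})

test_that("predominant TF follows the strongest single-deletion effect", {
  expect_equal(predominant_tf("G|A", c(G = -3.2, A = -1.1)), "G")
  expect_equal(predominant_tf("G|A", c(G = -2.0, A = -2.05)), c("G", "A"))
  # AND genes with weak single mutants: both fall in the tie band
  expect_equal(predominant_tf("G&A", c(G = -0.2, A = -0.1)), c("G", "A"))
  # wider margin separates them
  expect_equal(predominant_tf("G&A", c(G = -0.25, A = -0.1),
                              tie_margin = 0.1), "G")
  # single-TF expressions are trivial
  expect_equal(predominant_tf("R", c(G = -1)), "R")
  # missing single-mutant value -> undetermined
  out <- predominant_tf("G|A", c(G = -1))
  expect_length(out, 0)
  expect_true(attr(out, "undetermined"))
  # up-direction uses the maximum
  expect_equal(predominant_tf("G|A", c(G = 1.0, A = 2.5),
                              direction = "up"), "A")
})

test_that("Venn partition assigns regions by literals and conserves genes", {
  calls <- tibble::tibble(gene_id = c("g1", "g2", "g3", "g4", "g5"),
                          expression = c("G", "G|A", "G&A", "none",
                                         "complex"))
  v <- venn_partition(calls)
  counts <- setNames(v$n_genes, as.character(v$region))
  expect_equal(unname(counts["G"]), 1L)
  expect_equal(unname(counts["AG"]), 2L)
  expect_equal(unname(counts["none"]), 2L)
  expect_equal(sum(v$n_genes), nrow(calls))
  # all-none input
  v0 <- venn_partition(tibble::tibble(gene_id = c("a", "b"),
                                      expression = c("none", "none")))
  expect_equal(sum(v0$n_genes[v0$region != "none"]), 0L)
})

test_that("temporal switches compare canonicalized expressions", {
  early <- tibble::tibble(gene_id = c("g1", "g2", "g3", "g4"),
                          expression = c("G|A", "G", "A|G", "G"))
  late <- tibble::tibble(gene_id = c("g1", "g2", "g3", "g5"),
                         expression = c("G&R", "G", "G|A", "R"))
  sw <- temporal_switches(early, late)
  expect_true(sw$switched[sw$gene_id == "g1"])   # pmeA-style switch
  expect_false(sw$switched[sw$gene_id == "g2"])
  expect_false(sw$switched[sw$gene_id == "g3"])  # canonical forms equal
  expect_true(sw$one_sided[sw$gene_id == "g4"])
  expect_true(is.na(sw$switched[sw$gene_id == "g5"]))
})
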