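#' Median-of-ratios size factors
#'
#' For each sample, the median over genes (restricted to genes with a
#' nonzero count in every sample) of the ratio of the gene's count to its
#' across-sample geometric mean. The standard library-composition
#' normalization for count-based differential expression.
#'
#' @param counts Wide count tibble (`gene_id` + sample columns).
#' @return Named numeric vector of per-sample size factors (all > 0).
#' @export
#' @examples
#' cm <- tibble::tibble(gene_id = c("a", "b"), s1 = c(10L, 20L),
#'                      s2 = c(20L, 40L))
#' size_factors(cm)  # c(1, 2) / sqrt(2)
size_factors <- function(counts) {
  samples <- setdiff(names(counts), "gene_id")
  mat <- as.matrix(counts[, samples])
  keep <- rowSums(mat == 0) == 0
  if (!any(keep)) {
    abort("No gene has nonzero counts in every sample; cannot compute size factors.")
  }
  lg <- log(mat[keep, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(exp(lg - geo), 2, median)
  setNames(sf, samples)
}

## Method-of-moments NB dispersion pooled across the two groups (weights =
## within-group degrees of freedom), floored at `floor`.
pooled_dispersion <- function(groups, floor = 1e-8) {
  num <- 0; den <- 0
  for (y in groups) {
    n <- length(y)
    if (n < 2) next
    mu <- mean(y)
    if (mu <= 0) next
    a <- (var(y) - mu) / mu^2
    num <- num + (n - 1) * a
    den <- den + (n - 1)
  }
  if (den == 0) return(floor)
  max(num / den, floor)
}

#' Negative-binomial Wald test for one contrast
#'
#' Tests each gene for differential expression between one mutant genotype
#' and the reference at a timepoint. Counts are divided by the size
#' factors; `log2FC = log2((mean_mut + 0.5) / (mean_ref + 0.5))` with a
#' 0.5 pseudocount; the gene dispersion is a method-of-moments estimate
#' pooled across the two groups (floored at 1e-8); the Wald statistic
#' uses the delta-method standard error of the log2 ratio under
#' `Var(count) = mu + dispersion * mu^2`; p-values are two-sided normal.
#' Genes with zero counts in both groups get `p = 1`.
#'
#' @param counts Wide count tibble.
#' @param design Design tibble.
#' @param genotype Mutant genotype label (e.g. `"AG"`).
#' @param timepoint Timepoint label.
#' @param sf Size factors from [size_factors()] (computed if `NULL`).
#' @param disp_floor Lower bound for the dispersion estimate.
#' @return Tibble: `gene_id`, `genotype`, `timepoint`, `baseMean_ref`,
#'   `baseMean_mut`, `log2FC`, `dispersion`, `wald_z`, `p`.
#' @export
nb_test <- function(counts, design, genotype, timepoint, sf = NULL,
                    disp_floor = 1e-8) {
  validate_design(design)
  if (is.null(sf)) sf <- size_factors(counts)
  ref_ids <- design$sample_id[design$genotype == "ref" &
                                design$timepoint == timepoint]
  mut_ids <- design$sample_id[design$genotype == genotype &
                                design$timepoint == timepoint]
  if (length(ref_ids) == 0 || length(mut_ids) == 0) {
    abort(sprintf("Empty group for contrast %s vs ref at %s.",
                  genotype, timepoint))
  }
  yr <- sweep(as.matrix(counts[, ref_ids, drop = FALSE]), 2,
              sf[ref_ids], "/")
  ym <- sweep(as.matrix(counts[, mut_ids, drop = FALSE]), 2,
              sf[mut_ids], "/")
  mr <- rowMeans(yr); mm <- rowMeans(ym)
  l2fc <- log2((mm + 0.5) / (mr + 0.5))
  disp <- vapply(seq_len(nrow(counts)), function(i) {
    pooled_dispersion(list(yr[i, ], ym[i, ]), floor = disp_floor)
  }, numeric(1))
  ## NB delta-method variance of each group mean; never taken below the
  ## group's empirical variance, guarding against dispersion
  ## underestimation at small replicate numbers
  vr_emp <- apply(yr, 1, var); vm_emp <- apply(ym, 1, var)
  vr_emp[is.na(vr_emp)] <- 0; vm_emp[is.na(vm_emp)] <- 0
  var_mr <- pmax(mr + disp * mr^2, vr_emp) / length(ref_ids)
  var_mm <- pmax(mm + disp * mm^2, vm_emp) / length(mut_ids)
  se <- sqrt(var_mm / (mm + 0.5)^2 + var_mr / (mr + 0.5)^2) / log(2)
  z <- ifelse(se > 0, l2fc / se, 0)
  p <- 2 * pnorm(-abs(z))
  both_zero <- mr == 0 & mm == 0
  z[both_zero] <- 0
  p[both_zero] <- 1
  l2fc[both_zero] <- 0
  tibble(gene_id = counts$gene_id, genotype = genotype,
         timepoint = timepoint, baseMean_ref = mr, baseMean_mut = mm,
         log2FC = l2fc, dispersion = disp, wald_z = z, p = p)
}

#' Benjamini-Hochberg adjustment and regulation calls
#'
#' Adjusts p-values within each contrast (genotype x timepoint) and calls
#' each gene `down` when the fold change is below 1/`fc_threshold`
#' (strictly: `2^(-log2FC) > fc_threshold`) with `padj <= alpha`, `up`
#' symmetrically, `ns` otherwise. A fold change of exactly the threshold
#' is not called; an adjusted p of exactly `alpha` is.
#'
#' @param results DE rows from [nb_test()] (one or several contrasts
#'   bound together).
#' @param fc_threshold Fold-change cut-off (default 1.5).
#' @param alpha Adjusted-p cut-off (default 0.05).
#' @return Input with `padj` and `call` (`down`/`up`/`ns`) appended.
#' @export
adjust_and_call <- function(results, fc_threshold = 1.5, alpha = 0.05) {
  stopifnot(all(results$p >= 0 & results$p <= 1))
  out <- results |>
    dplyr::group_by(.data$genotype, .data$timepoint) |>
    dplyr::mutate(padj = p.adjust(.data$p, method = "BH")) |>
    dplyr::ungroup()
  fc <- 2^abs(out$log2FC)
  sig <- fc > fc_threshold & out$padj <= alpha
  out$call <- ifelse(sig & out$log2FC < 0, "down",
                     ifelse(sig & out$log2FC > 0, "up", "ns"))
  out
}

#' Run all mutant-vs-reference contrasts
#'
#' Applies [nb_test()] to each of the seven mutant genotypes at each
#' timepoint present in the design, then [adjust_and_call()].
#'
#' @inheritParams nb_test
#' @inheritParams adjust_and_call
#' @return Tibble of called DE results across all contrasts.
#' @export
de_all_contrasts <- function(counts, design, sf = NULL, fc_threshold = 1.5,
                             alpha = 0.05, disp_floor = 1e-8) {
  validate_design(design)
  if (is.null(sf)) sf <- size_factors(counts)
  combos <- expand.grid(genotype = intersect(MUTANT_ORDER,
                                             unique(design$genotype)),
                        timepoint = unique(design$timepoint),
                        stringsAsFactors = FALSE)
  res <- purrr::pmap(combos, function(genotype, timepoint) {
    nb_test(counts, design, genotype, timepoint, sf = sf,
            disp_floor = disp_floor)
  })
  adjust_and_call(dplyr::bind_rows(res), fc_threshold, alpha)
}
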