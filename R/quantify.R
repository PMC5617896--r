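#' Convert a count matrix to FPKM
#'
#' `FPKM_gs = counts_gs / (length_g / 1000) / (total_s / 1e6)`, with
#' `total_s` the column sum of the supplied counts ("total mapped
#' fragments" — multi-mapper removal is assumed to have happened upstream
#' of the count matrix). Per sample, `sum(FPKM * length_kb)` is exactly
#' 1e6.
#'
#' @param counts Wide tibble: `gene_id` plus one count column per sample.
#' @param lengths Tibble with `gene_id` and `length_bp` (an `fr_model`
#'   works).
#' @return Wide tibble of FPKM values, same shape as `counts`.
#' @export
#' @examples
#' counts <- tibble::tibble(gene_id = "g1", s1 = 10L)
#' lengths <- tibble::tibble(gene_id = "g1", length_bp = 1000L)
#' compute_fpkm(counts, lengths)  # 10 reads, 1 kb, 10 total -> depends on total
compute_fpkm <- function(counts, lengths) {
  stopifnot("gene_id" %in% names(counts),
            all(c("gene_id", "length_bp") %in% names(lengths)))
  samples <- setdiff(names(counts), "gene_id")
  len <- lengths$length_bp[match(counts$gene_id, lengths$gene_id)]
  if (anyNA(len)) abort("Some genes lack a length.")
  if (any(len <= 0)) abort("Gene lengths must be positive.")
  mat <- as.matrix(counts[, samples])
  if (any(mat < 0) || any(mat != round(mat))) {
    abort("Counts must be non-negative integers.")
  }
  totals <- colSums(mat)
  if (any(totals == 0)) {
    abort(sprintf("Sample(s) with zero total counts: %s",
                  paste(samples[totals == 0], collapse = ", ")))
  }
  fpkm <- sweep(mat / (len / 1000), 2, totals / 1e6, "/")
  dplyr::bind_cols(tibble(gene_id = counts$gene_id), as_tibble(fpkm))
}

#' Classify expression status from reference-strain FPKM
#'
#' Per gene and timepoint, the replicate-mean FPKM of the reference strain
#' determines status: below `thresholds[1]` (default 1) = `not_expressed`;
#' up to and including `thresholds[2]` (default 20) = `low`; above =
#' `expressed`. Both boundaries class as `low` (the "not expressed" cut is
#' a strict `FPKM < 1`).
#'
#' @param fpkm Wide FPKM tibble from [compute_fpkm()].
#' @param design Design tibble (columns `sample_id`, `genotype`,
#'   `timepoint`).
#' @param thresholds Length-2 numeric `(not_expressed_below, low_max)`.
#' @return Tibble: `gene_id`, `timepoint`, `ref_mean_fpkm`, `status`
#'   (factor `not_expressed` / `low` / `expressed`).
#' @export
expression_status <- function(fpkm, design, thresholds = c(1, 20)) {
  validate_design(design)
  out <- list()
  for (tp in unique(design$timepoint)) {
    ref <- design$sample_id[design$genotype == "ref" & design$timepoint == tp]
    if (length(ref) == 0) {
      abort(sprintf("No reference replicates at timepoint '%s'.", tp))
    }
    m <- rowMeans(as.matrix(fpkm[, ref, drop = FALSE]))
    status <- ifelse(m < thresholds[1], "not_expressed",
                     ifelse(m <= thresholds[2], "low", "expressed"))
    out[[tp]] <- tibble(gene_id = fpkm$gene_id, timepoint = tp,
                        ref_mean_fpkm = m,
                        status = factor(status, levels = c("not_expressed",
                                                           "low", "expressed")))
  }
  dplyr::bind_rows(out)
}

#' Replicate-averaged log expression matrix
#'
#' The matrix the heatmaps cluster: one column per genotype and timepoint,
#' value `log_base(mean-of-replicates FPKM + 1)`. Column names are
#' `genotype_timepoint`.
#'
#' @param fpkm Wide FPKM tibble.
#' @param design Design tibble.
#' @param base Logarithm base (default 2).
#' @return Wide tibble: `gene_id` plus one column per genotype x
#'   timepoint; all values >= 0.
#' @export
#' @examples
#' # duplicates 3 and 5 average to 4: log2(4 + 1) = 2.3219
mean_log_matrix <- function(fpkm, design, base = 2) {
  validate_design(design)
  groups <- unique(design[, c("genotype", "timepoint")])
  groups <- dplyr::arrange(groups, match(.data$genotype, genotype_labels()),
                           .data$timepoint)
  cols <- lapply(seq_len(nrow(groups)), function(i) {
    ids <- design$sample_id[design$genotype == groups$genotype[i] &
                              design$timepoint == groups$timepoint[i]]
    log(rowMeans(as.matrix(fpkm[, ids, drop = FALSE])) + 1, base = base)
  })
  names(cols) <- sprintf("%s_%s", groups$genotype, groups$timepoint)
  dplyr::bind_cols(tibble(gene_id = fpkm$gene_id), as_tibble(cols))
}
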