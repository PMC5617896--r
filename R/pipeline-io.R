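## Readers and writers for the pipeline's on-disk formats: TSV (tab
## separated, UTF-8, header row, "." for missing), FASTA via Biostrings,
## JSON summaries via jsonlite.

#' Write / read a pipeline TSV
#'
#' @param x Data frame.
#' @param path File path.
#' @return `path` (writer) or a tibble (reader).
#' @export
write_tsv_ <- function(x, path) {
  readr::write_tsv(x, path, na = ".")
  invisible(path)
}

#' @rdname write_tsv_
#' @export
read_tsv_ <- function(path) {
  readr::read_tsv(path, na = ".", show_col_types = FALSE, progress = FALSE)
}

#' Write / read promoters as FASTA
#'
#' One record per gene, record ID = `gene_id`.
#'
#' @param promoters Tibble with `gene_id` and `sequence` (or named
#'   character vector).
#' @param path File path.
#' @return `path` (writer); tibble `gene_id`, `sequence` (reader).
#' @export
write_promoters_fasta <- function(promoters, path) {
  v <- as_promoter_vector(promoters)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(v), path)
  invisible(path)
}

#' @rdname write_promoters_fasta
#' @export
read_promoters_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  tibble(gene_id = names(ss), sequence = unname(as.character(ss)))
}

#' Assemble a pipeline configuration
#'
#' Thresholds and parameters of the whole inference chain, with the
#' experiment's published cut-offs as defaults. A YAML file with the same keys
#' can be loaded via `yaml::read_yaml()` and splatted into this
#' constructor.
#'
#' @param fc Fold-change cut-off for DE calls (strict `>`).
#' @param alpha Adjusted-p cut-off (inclusive `<=`).
#' @param fpkm_not_expressed Reference FPKM below which a gene is not
#'   expressed (strict `<`).
#' @param fpkm_low_max Upper bound (inclusive) of the lowly-expressed
#'   band.
#' @param scan_p PWM site-calling p-value threshold (strict `<`).
#' @param motif_widths Length-2 integer range of discovery widths.
#' @param tie_margin Predominant-TF tie band (log2 units).
#' @param log_base Base of the heatmap log transform.
#' @param seed Integer seed for all stochastic stages.
#' @return List of class `fr_config`.
#' @export
pipeline_config <- function(fc = 1.5, alpha = 0.05,
                            fpkm_not_expressed = 1, fpkm_low_max = 20,
                            scan_p = 1e-4, motif_widths = c(6, 10),
                            tie_margin = 0.1, log_base = 2, seed = 1L) {
  stopifnot(fc > 0, alpha > 0, fpkm_not_expressed > 0, fpkm_low_max > 0,
            scan_p > 0, tie_margin >= 0, log_base > 1)
  if (any(motif_widths < 4) || any(motif_widths > 20)) {
    abort("motif_widths must lie within [4, 20].")
  }
  structure(list(fc = fc, alpha = alpha,
                 fpkm_not_expressed = fpkm_not_expressed,
                 fpkm_low_max = fpkm_low_max, scan_p = scan_p,
                 motif_widths = motif_widths, tie_margin = tie_margin,
                 log_base = log_base, seed = as.integer(seed)),
            class = "fr_config")
}
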