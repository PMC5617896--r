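#' Motif enrichment in a target set versus a background set
#'
#' Builds the 2x2 presence table (target with/without a hit, background
#' with/without), reports the presence proportions, the odds ratio
#' (cross-product; Haldane 0.5 correction applied to all cells when any
#' cell is zero) and the two-sided Fisher exact p-value. Inputs are
#' per-sequence hit indicators or, via [enrichment_from_counts()], the
#' counts themselves; the background may be disjoint from the target or
#' the genome-wide set.
#'
#' @param target Logical vector: per target sequence, does it carry a hit?
#' @param background Logical vector for the background set.
#' @return One-row tibble: `n_target_hit`, `n_target`, `n_bg_hit`,
#'   `n_bg`, `prop_target`, `prop_bg`, `odds_ratio`, `p_value`.
#' @export
#' @examples
#' enrichment_from_counts(28, 34, 3688, 11717)  # 82.4% vs 31.5%, OR ~ 10.2
motif_enrichment <- function(target, background) {
  if (length(target) == 0) abort("Empty target set.")
  enrichment_from_counts(sum(target), length(target),
                         sum(background), length(background))
}

#' @rdname motif_enrichment
#' @param n_target_hit,n_target,n_bg_hit,n_bg Counts of the 2x2 table
#'   margins: hits in the target set, target-set size, hits in the
#'   background set, background-set size.
#' @export
enrichment_from_counts <- function(n_target_hit, n_target, n_bg_hit, n_bg) {
  if (n_target <= 0) abort("Empty target set.")
  stopifnot(n_target_hit >= 0, n_bg_hit >= 0, n_bg >= 0,
            n_target_hit <= n_target, n_bg_hit <= n_bg)
  a <- n_target_hit; b <- n_target - n_target_hit
  c_ <- n_bg_hit;    d <- n_bg - n_bg_hit
  cells <- c(a, b, c_, d)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  p <- if (n_bg == 0) 1 else
    fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
  tibble(n_target_hit = a, n_target = n_target, n_bg_hit = c_, n_bg = n_bg,
         prop_target = a / n_target,
         prop_bg = if (n_bg > 0) c_ / n_bg else NA_real_,
         odds_ratio = or, p_value = p)
}
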