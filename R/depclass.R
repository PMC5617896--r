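#' Regulation pattern of genes across the seven deletion mutants
#'
#' Collapses per-contrast differential-expression calls into one 7-bit
#' pattern per gene and timepoint: bit *i* is `TRUE` when the gene is
#' called regulated in the stated direction in mutant genotype *i* versus
#' the reference. Genotypes are ordered `G, A, R, AG, AR, GR, AGR`
#' (see [genotype_labels()]).
#'
#' @param calls Data frame of DE calls as returned by [adjust_and_call()]:
#'   columns `gene_id`, `genotype`, `timepoint`, `call`.
#' @param timepoint Timepoint to extract (must be present in `calls`).
#' @param direction `"down"` (default) or `"up"`: which call counts as
#'   regulated.
#' @return Tibble with columns `gene_id`, `timepoint`, `direction` and one
#'   logical column per mutant genotype, in fixed order.
#' @export
down_pattern <- function(calls, timepoint, direction = c("down", "up")) {
  direction <- match.arg(direction)
  stopifnot(all(c("gene_id", "genotype", "timepoint", "call") %in% names(calls)))
  sub <- dplyr::filter(calls, .data$timepoint == !!timepoint)
  missing <- setdiff(MUTANT_ORDER, unique(sub$genotype))
  if (length(missing) > 0) {
    abort(sprintf("Missing contrast(s) at timepoint '%s': %s",
                  timepoint, paste(missing, collapse = ", ")))
  }
  wide <- sub |>
    dplyr::mutate(bit = .data$call == direction) |>
    dplyr::select("gene_id", "genotype", "bit") |>
    tidyr::pivot_wider(names_from = "genotype", values_from = "bit")
  wide <- wide[, c("gene_id", MUTANT_ORDER)]
  tibble(gene_id = wide$gene_id, timepoint = timepoint,
         direction = direction) |>
    dplyr::bind_cols(wide[, MUTANT_ORDER])
}

## Core inference on one named 7-bit pattern.  Extends the pattern to the
## full 8-genotype truth table (reference = FALSE); if the true-set is
## upward-closed under inclusion of deletion sets, the minimal monotone DNF
## is the disjunction of the minimal true deletion sets; otherwise the
## pattern cannot arise from monotone dependency and is labelled "complex".
infer_bits <- function(bits) {
  stopifnot(length(bits) == 7)
  bits <- as.logical(bits[MUTANT_ORDER])
  names(bits) <- MUTANT_ORDER
  if (!any(bits)) return(list(expression = "none", class = "none"))
  sets <- all_deletion_sets()
  true_sets <- sets[bits]
  ## upward closure: every superset of a true set must be true
  for (i in which(bits)) {
    for (j in seq_along(sets)) {
      if (i != j && is_subset(sets[[i]], sets[[j]]) && !bits[j]) {
        return(list(expression = "complex", class = "complex"))
      }
    }
  }
  clauses <- minimal_sets(true_sets)
  list(expression = dnf_string(clauses), class = dnf_class(clauses))
}

#' Infer the minimal monotone dependency expression from regulation patterns
#'
#' The core inference of the pipeline: each gene's 7-bit regulation pattern
#' over the mutant panel is mapped to the unique minimal monotone DNF over
#' the deletion literals G, A, R whose satisfied genotypes equal the
#' pattern. Patterns that are not upward-closed (a gene regulated in a
#' mutant but not in a strain deleting a superset of its TFs) cannot arise
#' from monotone activator dependency and are labelled `"complex"`; the
#' all-false pattern is `"none"`.
#'
#' The dependency class summarises the expression: `single` (one TF),
#' `and` (one multi-TF clause, e.g. only the double mutant responds),
#' `or` (several single TFs each sufficient), `mixed` (any other monotone
#' form), `none`, `complex`.
#'
#' @param patterns Tibble from [down_pattern()] (columns `gene_id`,
#'   `timepoint`, `direction`, plus the seven genotype bit columns).
#' @return The input with `expression` and `class` columns appended and the
#'   bit columns retained.
#' @export
#' @examples
#' pat <- tibble::tibble(gene_id = "g1", timepoint = "2h", direction = "down",
#'   G = TRUE, A = FALSE, R = FALSE, AG = TRUE, AR = FALSE, GR = TRUE,
#'   AGR = TRUE)
#' infer_dependency(pat)$expression  # "G"
infer_dependency <- function(patterns) {
  stopifnot(all(MUTANT_ORDER %in% names(patterns)))
  res <- lapply(seq_len(nrow(patterns)), function(i) {
    infer_bits(unlist(patterns[i, MUTANT_ORDER]))
  })
  patterns$expression <- vapply(res, `[[`, character(1), "expression")
  patterns$class <- vapply(res, `[[`, character(1), "class")
  as_tibble(patterns)
}

#' Predominant transcription factor of a combinatorially controlled gene
#'
#' Among the TFs named in a gene's dependency expression, the predominant
#' activator is the one whose single deletion has the strongest effect in
#' the call's direction; TFs within `tie_margin` log2 units of the extreme
#' are reported as a tie. For AND-type genes both single-mutant effects are
#' weak by construction, so a tie (or an empty set when values are missing)
#' is the documented outcome.
#'
#' @param expression Dependency expression string (e.g. `"G|A"`).
#' @param single_log2fc Named numeric vector of single-mutant log2
#'   fold-changes (mutant over reference) for at least the TFs named in
#'   `expression`; names are TF letters.
#' @param direction `"down"`: strongest = most negative; `"up"`: most
#'   positive.
#' @param tie_margin Width (log2 units) of the tie band around the extreme.
#' @return Character vector of predominant TF letters; empty with attribute
#'   `undetermined = TRUE` when a required single-mutant value is missing.
#' @export
#' @examples
#' predominant_tf("G|A", c(G = -3.2, A = -1.1))  # "G"
predominant_tf <- function(expression, single_log2fc,
                           direction = c("down", "up"), tie_margin = 0.1) {
  direction <- match.arg(direction)
  if (expression %in% c("none", "complex")) return(character(0))
  tfs <- sort_literals(unique(unlist(parse_dnf(expression))))
  if (length(tfs) == 1) return(tfs)
  vals <- single_log2fc[tfs]
  if (anyNA(vals) || length(vals) < length(tfs)) {
    out <- character(0)
    attr(out, "undetermined") <- TRUE
    return(out)
  }
  if (direction == "down") {
    keep <- vals <= min(vals) + tie_margin
  } else {
    keep <- vals >= max(vals) - tie_margin
  }
  sort_literals(tfs[keep])
}

#' Classify dependencies for a whole timepoint
#'
#' Convenience wrapper running [down_pattern()], [infer_dependency()] and
#' [predominant_tf()] over all genes of one timepoint and direction.
#' Single-mutant log2 fold-changes for predominance are taken from `calls`.
#'
#' @inheritParams down_pattern
#' @param tie_margin Passed to [predominant_tf()].
#' @return Tibble: `gene_id`, `timepoint`, `direction`, the seven bit
#'   columns, `expression`, `class`, `predominant` (comma-joined TF
#'   letters, `""` when empty or undetermined).
#' @export
classify_dependencies <- function(calls, timepoint,
                                  direction = c("down", "up"),
                                  tie_margin = 0.1) {
  direction <- match.arg(direction)
  dep <- infer_dependency(down_pattern(calls, timepoint, direction))
  lfc <- dplyr::filter(calls, .data$timepoint == !!timepoint,
                       .data$genotype %in% TF_ORDER)
  dep$predominant <- vapply(seq_len(nrow(dep)), function(i) {
    g <- dep$gene_id[i]
    v <- setNames(lfc$log2FC[lfc$gene_id == g], lfc$genotype[lfc$gene_id == g])
    paste(predominant_tf(dep$expression[i], v, direction, tie_margin),
          collapse = ",")
  }, character(1))
  dep
}

#' Partition dependent genes into the regions of the three-TF Venn diagram
#'
#' A gene belongs to circle X iff literal X appears in its dependency
#' expression; its region is the exact set of circles. Genes with
#' `"none"` or `"complex"` expressions are counted in the `none` bucket.
#'
#' @param calls Tibble with columns `gene_id` and `expression` (e.g. from
#'   [classify_dependencies()]).
#' @return Tibble `region` (`G`, `A`, `R`, `AG`, `AR`, `GR`, `AGR`,
#'   `none`), `n_genes`, list-column `genes`.
#' @export
venn_partition <- function(calls) {
  region_of <- function(expr) {
    if (expr %in% c("none", "complex")) return("none")
    genotype_label(sort_literals(unique(unlist(parse_dnf(expr)))))
  }
  regions <- vapply(calls$expression, region_of, character(1))
  lv <- c(MUTANT_ORDER, "none")
  tibble(
    region = factor(lv, levels = lv),
    n_genes = vapply(lv, function(r) sum(regions == r), integer(1)),
    genes = lapply(lv, function(r) calls$gene_id[regions == r])
  )
}

#' Detect genes whose dependency expression changes between timepoints
#'
#' Expressions are canonicalized ([canonical_dnf()]) before comparison, so
#' `"A|G"` and `"G|A"` do not count as a switch. Genes present at only one
#' timepoint are flagged `one_sided` and get `switched = NA`.
#'
#' @param calls_early,calls_late Tibbles with `gene_id` and `expression`
#'   columns (one per timepoint).
#' @return Tibble: `gene_id`, `expression_early`, `expression_late`,
#'   `switched`, `one_sided`.
#' @export
temporal_switches <- function(calls_early, calls_late) {
  e <- tibble(gene_id = calls_early$gene_id,
              expression_early = canonical_dnf(calls_early$expression))
  l <- tibble(gene_id = calls_late$gene_id,
              expression_late = canonical_dnf(calls_late$expression))
  dplyr::full_join(e, l, by = "gene_id") |>
    dplyr::mutate(
      one_sided = is.na(.data$expression_early) | is.na(.data$expression_late),
      switched = ifelse(.data$one_sided, NA,
                        .data$expression_early != .data$expression_late)
    )
}
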