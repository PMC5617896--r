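## Monotone Boolean (DNF) machinery over the three deletion indicators.
##
## A dependency expression is a monotone DNF over the literals G, A, R,
## where literal X is true for a genotype iff TF X is deleted in it.  A
## clause is a conjunction of literals; the DNF is the disjunction of its
## clauses.  Internally a DNF is a list of character vectors (one vector of
## TF letters per clause); the canonical string form writes literals in
## G, A, R order joined by "&", clauses sorted (fewest literals first, then
## literal order) and joined by "|", with multi-literal clauses
## parenthesised when there is more than one clause, e.g. "(G&A)|(G&R)".

sort_literals <- function(x) x[order(match(x, TF_ORDER))]

clause_key <- function(clause) {
  idx <- sort(match(clause, TF_ORDER))
  sprintf("%d-%s", length(clause), paste(idx, collapse = ""))
}

sort_clauses <- function(clauses) {
  clauses[order(vapply(clauses, clause_key, character(1)))]
}

#' Parse a dependency expression into clauses
#'
#' Accepts the canonical string form (e.g. `"G"`, `"G&A"`, `"G|A"`,
#' `"(G&A)|(G&R)"`); the unicode connectives `∧`/`∨` are accepted as
#' synonyms of `&`/`|`. `"none"` (or `""`) parses to an empty clause list.
#'
#' @param expr Dependency expression string.
#' @return List of character vectors, one per clause (literals sorted in
#'   G, A, R order), sorted canonically. `"complex"` is not parseable and
#'   raises an error.
#' @export
#' @examples
#' parse_dnf("(G&A)|(G&R)")
parse_dnf <- function(expr) {
  stopifnot(is.character(expr), length(expr) == 1)
  if (is.na(expr) || expr %in% c("none", "")) return(list())
  if (identical(expr, "complex")) {
    abort("'complex' is not a DNF and cannot be parsed.")
  }
  s <- gsub("∧", "&", expr)
  s <- gsub("∨", "|", s, fixed = TRUE)
  s <- gsub("[[:space:]()]", "", s)
  clauses <- strsplit(s, "|", fixed = TRUE)[[1]]
  clauses <- clauses[nzchar(clauses)]
  if (length(clauses) == 0) abort(sprintf("Empty DNF expression: '%s'", expr))
  parsed <- lapply(clauses, function(cl) {
    lits <- strsplit(cl, "&", fixed = TRUE)[[1]]
    bad <- setdiff(lits, TF_ORDER)
    if (length(bad) > 0 || length(lits) == 0) {
      abort(sprintf("Unknown literal(s) '%s' in clause '%s'",
                    paste(bad, collapse = ","), cl))
    }
    sort_literals(unique(lits))
  })
  sort_clauses(unique(parsed))
}

#' Format clauses as a canonical DNF string
#'
#' @param clauses List of character vectors of TF letters (one per clause).
#' @return Canonical string; `"none"` for an empty clause list.
#' @export
dnf_string <- function(clauses) {
  if (length(clauses) == 0) return("none")
  clauses <- sort_clauses(lapply(clauses, function(cl) sort_literals(unique(cl))))
  parts <- vapply(clauses, paste, character(1), collapse = "&")
  if (length(parts) == 1) return(parts)
  parts <- ifelse(lengths(clauses) > 1, paste0("(", parts, ")"), parts)
  paste(parts, collapse = "|")
}

#' Canonicalize a dependency expression
#'
#' Sorts literals within clauses and clauses within the expression so that
#' logically identical strings compare equal (`"A|G"` and `"G|A"` both
#' canonicalize to `"G|A"`). `"none"` and `"complex"` pass through.
#'
#' @param expr Dependency expression string (vectorised).
#' @return Canonical string(s).
#' @export
canonical_dnf <- function(expr) {
  vapply(expr, function(e) {
    if (is.na(e)) return(NA_character_)
    if (e %in% c("none", "", "complex")) return(ifelse(e == "", "none", e))
    dnf_string(parse_dnf(e))
  }, character(1), USE.NAMES = FALSE)
}

#' Evaluate a dependency expression on a deletion genotype
#'
#' A clause is satisfied when every TF it names is deleted; the DNF is true
#' when any clause is satisfied. `"none"` is always false; `"complex"`
#' evaluates to `NA`.
#'
#' @param expr Dependency expression string.
#' @param deleted Character vector of deleted TF letters, or a genotype
#'   label such as `"AG"` or `"ref"`.
#' @return Logical scalar.
#' @export
#' @examples
#' eval_dnf("G&A", "AG")   # TRUE
#' eval_dnf("G&A", "G")    # FALSE
eval_dnf <- function(expr, deleted) {
  if (length(deleted) == 1 && (deleted %in% c(genotype_labels(), "")))
    deleted <- genotype_deleted(deleted)
  if (identical(expr, "complex")) return(NA)
  clauses <- parse_dnf(expr)
  any(vapply(clauses, function(cl) all(cl %in% deleted), logical(1)))
}

## All non-empty subsets of the TF set, as sorted letter vectors.
all_deletion_sets <- function() {
  lapply(MUTANT_ORDER, genotype_deleted)
}

is_subset <- function(a, b) all(a %in% b)

## Minimal elements (under set inclusion) of a list of sets.
minimal_sets <- function(sets) {
  keep <- vapply(seq_along(sets), function(i) {
    !any(vapply(seq_along(sets), function(j) {
      j != i && is_subset(sets[[j]], sets[[i]]) &&
        length(sets[[j]]) < length(sets[[i]])
    }, logical(1)))
  }, logical(1))
  sets[keep]
}

## Enumerate every monotone Boolean function on {G,A,R} with f(reference) =
## FALSE, as its minimal DNF (an antichain of non-empty deletion sets).
## There are 19: the 20 monotone functions on three variables minus the
## constant-TRUE one, which would require the reference strain to count as
## regulated against itself.  Used by the generator to sample dependencies
## of a requested class.
monotone_dnfs <- function() {
  sets <- all_deletion_sets()
  out <- list(list())                        # the constant-FALSE function
  n <- length(sets)
  for (mask in seq_len(2^n - 1)) {
    chosen <- sets[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    ## keep only antichains (no clause contained in another)
    anti <- TRUE
    if (length(chosen) > 1) {
      for (i in seq_along(chosen)) {
        for (j in seq_along(chosen)) {
          if (i != j && is_subset(chosen[[i]], chosen[[j]])) anti <- FALSE
        }
      }
    }
    if (anti) out[[length(out) + 1]] <- sort_clauses(chosen)
  }
  out
}

## Classify a clause list into the dependency class vocabulary.
dnf_class <- function(clauses) {
  if (length(clauses) == 0) return("none")
  sizes <- lengths(clauses)
  if (length(clauses) == 1) {
    if (sizes == 1) "single" else "and"
  } else {
    if (all(sizes == 1)) "or" else "mixed"
  }
}
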