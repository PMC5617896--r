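## Small shared helpers.

#' Reverse complement of DNA strings
#'
#' Plain-character convenience wrapper (A/C/G/T/N, case preserved for
#' upper case input); vectorised.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgtN", "TGCAtgcaN", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## Largest-remainder apportionment of n into the given proportions;
## guarantees the counts sum to n and equal round(n * p) when those rounds
## already sum to n.
apportion <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  setNames(as.integer(base), names(p))
}

## Coerce promoter inputs (named character vector, tibble with
## gene_id/seq_id + sequence, or Biostrings::DNAStringSet) to a named
## uppercase character vector.
as_promoter_vector <- function(seqs) {
  if (inherits(seqs, "DNAStringSet")) {
    out <- as.character(seqs)
  } else if (is.data.frame(seqs)) {
    idcol <- intersect(c("seq_id", "gene_id"), names(seqs))[1]
    if (is.na(idcol) || !"sequence" %in% names(seqs)) {
      abort("Promoter data frame needs a 'seq_id' or 'gene_id' column and a 'sequence' column.")
    }
    out <- setNames(seqs$sequence, seqs[[idcol]])
  } else if (is.character(seqs)) {
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
    out <- seqs
  } else {
    abort("Unsupported promoter container.")
  }
  toupper(out)
}

check_background <- function(background) {
  if (!all(c("A", "C", "G", "T") %in% names(background))) {
    abort("background must be named with A, C, G, T.")
  }
  background <- background[c("A", "C", "G", "T")]
  if (abs(sum(background) - 1) > 1e-9 || any(background < 0)) {
    abort("background frequencies must be non-negative and sum to 1.")
  }
  background
}
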