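IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Parse a degenerate (IUPAC) motif pattern
#'
#' Accepts single bases, bracketed sets (`"TG[CAG][GTA]GGG"`) and
#' single-letter IUPAC ambiguity codes (`N`, `R`, `Y`, ...), case
#' insensitively.
#'
#' @param pattern Motif string.
#' @param motif_id Optional identifier (defaults to the pattern itself).
#' @return Object of class `fr_iupac`: `motif_id`, `pattern`, `width`,
#'   `sets` (list of allowed-letter sets per position).
#' @export
#' @examples
#' parse_iupac("TG[CAG][GTA]GGG")$width  # 7
parse_iupac <- function(pattern, motif_id = NULL) {
  if (!is.character(pattern) || length(pattern) != 1 || !nzchar(pattern)) {
    abort("Motif pattern must be a non-empty string.")
  }
  chars <- strsplit(toupper(pattern), "")[[1]]
  sets <- list()
  i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1
      set <- character(0)
      while (j <= length(chars) && chars[j] != "]") {
        if (!chars[j] %in% c("A", "C", "G", "T")) {
          abort(sprintf("Unknown character '%s' at position %d of '%s'",
                        chars[j], j, pattern))
        }
        set <- c(set, chars[j])
        j <- j + 1
      }
      if (j > length(chars)) {
        abort(sprintf("Unclosed bracket at position %d of '%s'", i, pattern))
      }
      if (length(set) == 0) {
        abort(sprintf("Empty bracket at position %d of '%s'", i, pattern))
      }
      sets[[length(sets) + 1]] <- unique(set)
      i <- j + 1
    } else if (!is.null(IUPAC_CODES[[ch]])) {
      sets[[length(sets) + 1]] <- IUPAC_CODES[[ch]]
      i <- i + 1
    } else {
      abort(sprintf("Unknown character '%s' at position %d of '%s'",
                    ch, i, pattern))
    }
  }
  structure(list(motif_id = motif_id %||% pattern, pattern = pattern,
                 width = length(sets), sets = sets),
            class = "fr_iupac")
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

## Reverse complement of a parsed IUPAC motif.
iupac_revcomp <- function(motif) {
  sets <- lapply(rev(motif$sets), function(s) unname(COMPLEMENT[s]))
  structure(list(motif_id = motif$motif_id, pattern = NA_character_,
                 width = motif$width, sets = sets),
            class = "fr_iupac")
}

iupac_regex <- function(motif) {
  paste(vapply(motif$sets, function(s) {
    if (length(s) == 1) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1)), collapse = "")
}

## Leftmost 1-based start positions of all (overlapping) matches.
regex_starts <- function(seq, rx) {
  m <- gregexpr(paste0("(?=", rx, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Scan promoters for exact matches of a degenerate motif
#'
#' Reports every (overlapping) window matching the motif on either strand.
#' A minus-strand hit is a match of the pattern against the reverse
#' complement of the sequence; its `start` is the leftmost forward-strand
#' coordinate of the window and `match` is reported in motif orientation
#' (i.e. the reverse complement of the forward-strand window). `N` in a
#' sequence never matches. `upstream_position = L - start + 1` — the
#' distance from the start codon (right end of a promoter of length `L`)
#' to the leftmost base of the window.
#'
#' @param seqs Promoters: named character vector, tibble with
#'   `gene_id`/`seq_id` + `sequence`, or a `Biostrings::DNAStringSet`.
#' @param motif `fr_iupac` object or pattern string.
#' @param strands Strands to scan.
#' @return Tibble: `seq_id`, `motif_id`, `strand`, `start`,
#'   `upstream_position`, `match`.
#' @export
#' @examples
#' scan_iupac(c(p1 = "AAACCGCCAATTT"), "CC[ACTG]CCAA")
scan_iupac <- function(seqs, motif, strands = c("+", "-")) {
  if (is.character(motif)) motif <- parse_iupac(motif)
  seqs <- as_promoter_vector(seqs)
  rx_fwd <- iupac_regex(motif)
  rx_rev <- iupac_regex(iupac_revcomp(motif))
  w <- motif$width
  out <- list()
  for (id in names(seqs)) {
    s <- seqs[[id]]
    L <- nchar(s)
    if ("+" %in% strands) {
      for (st in regex_starts(s, rx_fwd)) {
        out[[length(out) + 1]] <- tibble(
          seq_id = id, motif_id = motif$motif_id, strand = "+",
          start = st, upstream_position = L - st + 1,
          match = substr(s, st, st + w - 1))
      }
    }
    if ("-" %in% strands) {
      for (st in regex_starts(s, rx_rev)) {
        out[[length(out) + 1]] <- tibble(
          seq_id = id, motif_id = motif$motif_id, strand = "-",
          start = st, upstream_position = L - st + 1,
          match = revcomp(substr(s, st, st + w - 1)))
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(seq_id = character(), motif_id = character(),
                  strand = character(), start = integer(),
                  upstream_position = integer(), match = character()))
  }
  dplyr::bind_rows(out)
}

#' Published GaaR, AraR and RhaR promoter elements
#'
#' The degenerate binding elements used for promoter annotation: the GaaR
#' regulatory element (GARE), two AraR elements (a CT-rich 15-mer and a
#' CCCC-core element), and the RhaR element discovered from RhaR-dependent
#' promoters.
#'
#' @return Tibble: `tf` (TF letter), `motif_id`, `pattern`, `width`.
#' @export
#' @examples
#' tf_motifs()
tf_motifs <- function() {
  pat <- c(
    GARE = "CC[ACGT]CCAA",
    AraR_CCCC = "CCCC[ATCG]CC",
    AraR_CTrich = paste0("[CTG][TC][TCA][CT][TC][CTA][CT][TCG]",
                         "[TC][CT][TC][CTA][TA][CT][CT]"),
    RhaR = "TG[CAG][GTA]GGG"
  )
  tibble(
    tf = c("G", "A", "A", "R"),
    motif_id = names(pat),
    pattern = unname(pat),
    width = vapply(unname(pat), function(p) parse_iupac(p)$width,
                   numeric(1), USE.NAMES = FALSE)
  )
}

#' Default one-motif-per-TF map
#'
#' The planted-motif map used by [generate_promoters()]: GARE for GaaR,
#' the CCCC-core element for AraR, and the RhaR element.
#'
#' @return Named character vector (names `G`, `A`, `R`).
#' @export
tf_motif_patterns <- function() {
  tm <- tf_motifs()
  c(G = tm$pattern[tm$motif_id == "GARE"],
    A = tm$pattern[tm$motif_id == "AraR_CCCC"],
    R = tm$pattern[tm$motif_id == "RhaR"])
}

#' Cross-species conservation of a motif in ortholog promoters
#'
#' For each species' set of ortholog promoters, the fraction of promoters
#' with at least one motif match (either strand) and a majority flag
#' (fraction > 0.5). Empty species sets are skipped with a warning.
#'
#' @param ortholog_promoters Named list of promoter sets (one per
#'   species), each in any format [scan_iupac()] accepts.
#' @param motif `fr_iupac` or pattern string.
#' @return Tibble: `species`, `n_promoters`, `n_with_hit`, `fraction`,
#'   `majority`.
#' @export
conservation_scan <- function(ortholog_promoters, motif) {
  if (is.character(motif)) motif <- parse_iupac(motif)
  out <- list()
  for (sp in names(ortholog_promoters)) {
    raw <- ortholog_promoters[[sp]]
    n_raw <- if (is.data.frame(raw)) nrow(raw) else length(raw)
    if (n_raw == 0) {
      warn(sprintf("Species '%s' has no promoters; skipped.", sp))
      next
    }
    seqs <- as_promoter_vector(raw)
    hits <- scan_iupac(seqs, motif)
    nh <- length(unique(hits$seq_id))
    out[[sp]] <- tibble(species = sp, n_promoters = length(seqs),
                        n_with_hit = nh, fraction = nh / length(seqs),
                        majority = nh / length(seqs) > 0.5)
  }
  dplyr::bind_rows(out)
}
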