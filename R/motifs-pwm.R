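## Position weight matrices with exact scan p-values.
##
## Scores are log2 odds (motif probability over 0-order background).  The
## null distribution of a window score is computed exactly by dynamic
## programming over the per-position score distributions after discretizing
## log-odds to a fixed granularity (default 1e-3 bits), so a reported
## p-value is the exact background probability of scoring at least as high
## at that granularity.

DNA4 <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' @param probs `width x 4` matrix of per-position letter probabilities
#'   (columns A, C, G, T); each row must sum to 1.
#' @param background Named 0-order background frequencies summing to 1.
#' @param motif_id Optional identifier.
#' @param pseudocount Pseudocount already applied (metadata only).
#' @return Object of class `fr_pwm` with a `logodds` (log2) matrix.
#' @export
new_pwm <- function(probs, background = c(A = 0.25, C = 0.25, G = 0.25,
                                          T = 0.25),
                    motif_id = "pwm", pseudocount = NA_real_) {
  probs <- as.matrix(probs)
  colnames(probs) <- DNA4
  background <- check_background(background)
  if (any(abs(rowSums(probs) - 1) > 1e-9) || any(probs < 0)) {
    abort("Each PWM row must be a probability distribution.")
  }
  structure(list(motif_id = motif_id, probs = probs,
                 background = background, pseudocount = pseudocount,
                 logodds = log2(sweep(probs, 2, background, "/")),
                 width = nrow(probs)),
            class = "fr_pwm")
}

#' PWM from aligned binding sites
#'
#' @param sites Character vector of equal-length site sequences.
#' @param pseudocount Added per letter cell before normalization
#'   (default 0.25).
#' @inheritParams new_pwm
#' @return `fr_pwm`.
#' @export
pwm_from_sites <- function(sites, pseudocount = 0.25,
                           background = c(A = 0.25, C = 0.25, G = 0.25,
                                          T = 0.25),
                           motif_id = "sites") {
  w <- unique(nchar(sites))
  if (length(w) != 1) abort("All sites must have equal length.")
  mat <- do.call(rbind, strsplit(toupper(sites), ""))
  counts <- sapply(DNA4, function(l) colSums(mat == l))
  probs <- (counts + pseudocount) / (rowSums(counts) + 4 * pseudocount)
  new_pwm(probs, background, motif_id, pseudocount)
}

#' PWM from a degenerate IUPAC pattern
#'
#' Allowed letters at each position share probability equally; a small
#' pseudocount keeps disallowed letters scoreable (needed for the exact
#' p-value computation).
#'
#' @param motif `fr_iupac` or pattern string.
#' @param pseudocount Probability mass smoothing per letter (default 0.01).
#' @inheritParams new_pwm
#' @return `fr_pwm`.
#' @export
pwm_from_iupac <- function(motif, pseudocount = 0.01,
                           background = c(A = 0.25, C = 0.25, G = 0.25,
                                          T = 0.25)) {
  if (is.character(motif)) motif <- parse_iupac(motif)
  probs <- t(vapply(motif$sets, function(set) {
    p <- setNames(rep(0, 4), DNA4)
    p[set] <- 1 / length(set)
    (p + pseudocount) / (1 + 4 * pseudocount)
  }, numeric(4)))
  new_pwm(probs, background, motif$motif_id, pseudocount)
}

## Reverse complement of a PWM; the background is complement-swapped so
## minus-strand p-values are exact under the same forward-strand model.
pwm_revcomp <- function(pwm) {
  probs <- pwm$probs[rev(seq_len(pwm$width)), c("T", "G", "C", "A"),
                     drop = FALSE]
  colnames(probs) <- DNA4
  bg <- pwm$background[c("T", "G", "C", "A")]
  names(bg) <- DNA4
  new_pwm(probs, bg, pwm$motif_id, pwm$pseudocount)
}

## Exact null score distribution by DP.  Returns integer-score support
## (offset + granularity) and the tail probability P(score >= s).
pwm_score_dist <- function(pwm, granularity = 1e-3) {
  if (any(pwm$probs == 0)) {
    abort("PWM has zero probabilities; use a pseudocount for exact p-values.")
  }
  S <- round(pwm$logodds / granularity)
  bg <- pwm$background
  lo <- sum(apply(S, 1, min))
  hi <- sum(apply(S, 1, max))
  dist <- numeric(hi - lo + 1)
  ## start: a zero score before any position, placed at offset -lo
  cur_lo <- 0
  cur <- 1
  for (i in seq_len(nrow(S))) {
    new_lo <- cur_lo + min(S[i, ])
    new_hi <- cur_lo + length(cur) - 1 + max(S[i, ])
    new <- numeric(new_hi - new_lo + 1)
    for (l in seq_len(4)) {
      sh <- cur_lo + S[i, l] - new_lo
      idx <- seq_along(cur) + sh
      new[idx] <- new[idx] + bg[l] * cur
    }
    cur <- new
    cur_lo <- new_lo
  }
  tail <- rev(cumsum(rev(cur)))
  list(granularity = granularity, min_int = cur_lo,
       max_int = cur_lo + length(cur) - 1, density = cur, tail = tail)
}

## p-value of integer scores under a score distribution.
pwm_tail_p <- function(dist, int_score) {
  idx <- int_score - dist$min_int + 1
  p <- numeric(length(int_score))
  p[idx <= 0] <- 1
  p[idx > length(dist$tail)] <- 0
  ok <- idx >= 1 & idx <= length(dist$tail)
  p[ok] <- dist$tail[idx[ok]]
  p
}

#' Scan promoters with a PWM at an exact p-value threshold
#'
#' Scores every window on both strands with the log2-odds matrix and keeps
#' windows whose exact background p-value (probability that a
#' background-generated window scores at least as high) is below
#' `p_threshold`. Windows containing `N` are skipped. Coordinates follow
#' the [scan_iupac()] convention.
#'
#' @param seqs Promoters (any format [scan_iupac()] accepts).
#' @param pwm `fr_pwm`.
#' @param p_threshold Keep hits with `p < p_threshold` (default 1e-4, the
#'   site-calling cut-off used for RhaR binding sites).
#' @param strands Strands to scan.
#' @param granularity Log-odds discretization in bits (default 1e-3).
#' @return Tibble: `seq_id`, `motif_id`, `strand`, `start`,
#'   `upstream_position`, `match`, `score` (bits), `p`.
#' @export
pwm_scan <- function(seqs, pwm, p_threshold = 1e-4, strands = c("+", "-"),
                     granularity = 1e-3) {
  seqs <- as_promoter_vector(seqs)
  present <- unique(unlist(strsplit(paste(seqs, collapse = ""), "")))
  if (any(pwm$background[intersect(present, DNA4)] == 0)) {
    abort("Background frequency 0 for a letter present in the sequences.")
  }
  scans <- list(`+` = pwm, `-` = pwm_revcomp(pwm))
  out <- list()
  for (strand in intersect(strands, c("+", "-"))) {
    pw <- scans[[strand]]
    dist <- pwm_score_dist(pw, granularity)
    S <- round(pw$logodds / granularity)
    w <- pw$width
    for (id in names(seqs)) {
      x <- match(strsplit(seqs[[id]], "")[[1]], DNA4)
      L <- length(x)
      if (L < w) next
      nwin <- L - w + 1
      sc <- rep(0L, nwin)
      bad <- rep(FALSE, nwin)
      for (k in seq_len(w)) {
        xi <- x[k:(k + nwin - 1)]
        bad <- bad | is.na(xi)
        v <- S[k, ifelse(is.na(xi), 1, xi)]
        sc <- sc + v
      }
      p <- pwm_tail_p(dist, sc)
      keep <- which(!bad & p < p_threshold)
      for (j in keep) {
        win <- substr(seqs[[id]], j, j + w - 1)
        out[[length(out) + 1]] <- tibble(
          seq_id = id, motif_id = pwm$motif_id, strand = strand,
          start = j, upstream_position = L - j + 1,
          match = if (strand == "+") win else revcomp(win),
          score = sc[j] * granularity, p = p[j])
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(seq_id = character(), motif_id = character(),
                  strand = character(), start = integer(),
                  upstream_position = integer(), match = character(),
                  score = numeric(), p = numeric()))
  }
  dplyr::bind_rows(out)
}
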