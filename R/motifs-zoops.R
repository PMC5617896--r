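## ZOOPS-EM motif discovery: each sequence harbours zero or one motif
## occurrence; a mixture over site positions with a 0-order background.
## The E-step computes, per sequence, the posterior of "no site" and of a
## site at each position; the M-step re-estimates the letter probabilities
## (pseudocount-smoothed) and the per-sequence site prior gamma.  The
## observed-data log likelihood (relative to the all-background model) is
## non-decreasing across iterations — checked on every run.
##
## The E/M steps are vectorized over all windows of all sequences at once
## (one stacked window-index matrix), which makes a generous seed search
## affordable: candidate seed w-mers are shortlisted by sequence frequency
## and re-ranked by the likelihood reached after two EM iterations —
## necessary because a degenerate motif spreads its instances over many
## distinct w-mers, so no single one is frequent.

encode_seqs <- function(seqs) {
  lapply(seqs, function(s) match(strsplit(s, "")[[1]], DNA4))
}

letter_freqs <- function(enc) {
  tab <- tabulate(unlist(enc), nbins = 4)
  setNames(tab / sum(tab), DNA4)
}

## Stacked window-index data for one width: X is (total windows) x w with
## the letter code of each window position; windows containing N are
## dropped.  seq_of maps window rows to sequences; m gives the number of
## valid windows per sequence.
zoops_window_data <- function(enc, w) {
  xs <- list(); seq_of <- list()
  for (i in seq_along(enc)) {
    x <- enc[[i]]
    nwin <- length(x) - w + 1
    if (nwin < 1) next
    idx <- vapply(seq_len(w), function(k) x[k:(k + nwin - 1)],
                  integer(nwin))
    idx <- matrix(idx, nrow = nwin)
    ok <- rowSums(is.na(idx)) == 0
    if (!any(ok)) next
    xs[[length(xs) + 1]] <- idx[ok, , drop = FALSE]
    seq_of[[length(seq_of) + 1]] <- rep(i, sum(ok))
  }
  X <- do.call(rbind, xs)
  seq_of <- unlist(seq_of)
  m <- tabulate(seq_of, nbins = length(enc))
  list(X = X, seq_of = seq_of, m = m, n_seq = length(enc), w = w)
}

zoops_em_run <- function(wd, theta, bg, gamma = 0.5, em_iters = 50,
                         tol = 1e-6, pseudocount = 0.25) {
  w <- wd$w
  n <- wd$n_seq
  nwin <- nrow(wd$X)
  kk <- rep(seq_len(w), each = nwin)
  ll_trace <- numeric(0)
  prev <- -Inf
  q <- numeric(n)
  sc <- NULL
  lik <- NULL
  for (it in seq_len(em_iters)) {
    lr <- log(sweep(theta, 2, bg, "/"))
    sc <- rowSums(matrix(lr[cbind(kk, c(wd$X))], nwin, w))
    ws <- exp(sc)
    S <- numeric(n)
    agg <- rowsum(ws, wd$seq_of)
    S[as.integer(rownames(agg))] <- agg[, 1]
    lik <- ifelse(wd$m > 0, (1 - gamma) + (gamma / pmax(wd$m, 1)) * S, 1)
    ll <- sum(log(lik))
    ll_trace <- c(ll_trace, ll)
    ## E-step window weights and M-step updates
    zw <- (gamma / wd$m[wd$seq_of]) * ws / lik[wd$seq_of]
    counts <- matrix(0, w, 4)
    for (k in seq_len(w)) {
      add <- rowsum(zw, wd$X[, k])
      counts[k, as.integer(rownames(add))] <- add[, 1]
    }
    q <- ifelse(wd$m > 0, (gamma / pmax(wd$m, 1)) * S / lik, 0)
    theta <- (counts + pseudocount) / (rowSums(counts) + 4 * pseudocount)
    gamma <- min(max(mean(q), 1e-6), 1 - 1e-6)
    if (it > 1 && abs(ll - prev) < tol) break
    prev <- ll
  }
  ## MAP site position per sequence under the final responsibilities
  map_pos <- rep(NA_integer_, n)
  ord <- order(wd$seq_of, -sc)
  first <- ord[!duplicated(wd$seq_of[ord])]
  win_start <- sequence(wd$m)   # window rank within sequence is not the
  ## promoter coordinate when N-windows were dropped; recover coordinates
  ## from the row index within each sequence block
  map_pos[wd$seq_of[first]] <- win_start[first]
  list(theta = theta, gamma = gamma, ll = ll_trace[length(ll_trace)],
       ll_trace = ll_trace, site_posterior = q, map_pos = map_pos)
}

#' Consensus string of a probability matrix
#'
#' @param probs `width x 4` matrix (columns A, C, G, T).
#' @return Most probable letter at each position, as one string.
#' @export
consensus_string <- function(probs) {
  paste(DNA4[apply(probs, 1, which.max)], collapse = "")
}

#' Hamming distance between equal-length strings
#'
#' @param a,b Strings of equal length.
#' @return Number of differing positions.
#' @export
hamming_dist <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' ZOOPS-EM motif discovery
#'
#' Discovers one motif per candidate width by expectation-maximization
#' under the zero-or-one-occurrence-per-sequence (ZOOPS) model, the model
#' used to find the RhaR element in 34 target promoters. For each width,
#' candidate seed w-mers are shortlisted by the number of sequences
#' containing them, re-ranked by the ZOOPS likelihood reached after two EM
#' iterations (a degenerate motif spreads its instances over many distinct
#' w-mers, so frequency alone cannot find it), and the top `n_seeds` are
#' run to convergence; the best run per width is kept. Across widths,
#' motifs are ranked by the ZOOPS log-likelihood ratio against the
#' background-only model; motifs below `llr_min` are dropped — the
#' package's stand-in for an E-value threshold. Note that the raw LLR
#' grows with motif width (more free parameters), so when comparing
#' widths the per-width motifs should be inspected, not only the overall
#' top. Discovery operates on the forward strand.
#'
#' @param seqs Promoters (any format [scan_iupac()] accepts); at least 5.
#' @param width_range Motif widths to try (default 6 to 10).
#' @param n_seeds Seeds run to full convergence per width.
#' @param n_shortlist Candidate seed w-mers entering the two-iteration
#'   re-ranking (default 500).
#' @param em_iters Maximum EM iterations.
#' @param tol Log-likelihood convergence tolerance.
#' @param pseudocount Letter pseudocount in the M-step (default 0.25).
#' @param llr_min Keep motifs with log-likelihood ratio at least this
#'   (default 0).
#' @param seed Integer seed (the search is deterministic; the seed covers
#'   residual tie-breaking).
#' @return Object of class `fr_zoops`: list with `motifs` (each with
#'   `width`, `probs`, `consensus`, `gamma`, `nsites`, `llr`,
#'   `ll_trace`, `sites` tibble of per-sequence posteriors and MAP
#'   positions), `background`, and `ranked` tibble. Supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
zoops_discover <- function(seqs, width_range = c(6, 10), n_seeds = 8,
                           n_shortlist = 500, em_iters = 50, tol = 1e-6,
                           pseudocount = 0.25, llr_min = 0, seed = 1L) {
  seqs <- as_promoter_vector(seqs)
  if (length(seqs) < 5) abort("ZOOPS discovery needs at least 5 sequences.")
  enc <- encode_seqs(seqs)
  if (min(lengths(enc)) <= max(width_range)) {
    abort("Every sequence must be longer than the maximum motif width.")
  }
  bg <- letter_freqs(enc)
  if (any(bg == 0)) {
    abort("Degenerate input: some letter never occurs; no motif can be fit.")
  }
  if (sum(bg > 0.999) > 0) {
    abort("Degenerate input (single-letter sequences); no motif.")
  }

  seed_theta <- function(kmer, w) {
    idx <- match(strsplit(kmer, "")[[1]], DNA4)
    th <- matrix(0.1, w, 4)
    th[cbind(seq_len(w), idx)] <- 0.7
    th
  }

  withr::with_seed(seed, {
    motifs <- list()
    for (w in seq(width_range[1], width_range[2])) {
      wd <- zoops_window_data(enc, w)
      ## shortlist seed w-mers by Hamming<=1 sequence support: a
      ## degenerate motif spreads its instances over many w-mer variants,
      ## so raw frequency misses them while the 1-mismatch neighbourhood
      ## pools their counts
      wm_by_seq <- lapply(seqs, function(s) {
        n <- nchar(s)
        if (n < w) return(character(0))
        unique(substring(s, 1:(n - w + 1), w:n))
      })
      tab <- table(unlist(wm_by_seq))
      tab <- tab[!grepl("N", names(tab))]
      cnt <- setNames(as.integer(tab), names(tab))
      cand <- names(cnt)
      total <- integer(length(cand))
      for (p in seq_len(w)) {
        pre <- substr(cand, 1, p - 1)
        post <- substr(cand, p + 1, w)
        for (l in DNA4) {
          v <- cnt[match(paste0(pre, l, post), cand)]
          v[is.na(v)] <- 0L
          total <- total + v
        }
      }
      supp <- total - (w - 1L) * cnt
      short <- cand[order(-supp, -cnt, cand)][
        seq_len(min(n_shortlist, length(cand)))]
      ## re-rank by the likelihood reached after two EM iterations
      probe <- vapply(short, function(km) {
        zoops_em_run(wd, seed_theta(km, w), bg, em_iters = 2,
                     pseudocount = pseudocount)$ll
      }, numeric(1))
      top <- short[order(-probe, short)][seq_len(min(n_seeds,
                                                     length(short)))]
      runs <- lapply(top, function(km) {
        zoops_em_run(wd, seed_theta(km, w), bg, em_iters = em_iters,
                     tol = tol, pseudocount = pseudocount)
      })
      best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "ll"))]]
      motifs[[length(motifs) + 1]] <- list(
        width = w, probs = best$theta,
        consensus = consensus_string(best$theta),
        gamma = best$gamma, nsites = sum(best$site_posterior),
        llr = best$ll, ll_trace = best$ll_trace,
        sites = tibble(seq_id = names(seqs),
                       posterior = best$site_posterior,
                       map_start = best$map_pos))
    }
    llrs <- vapply(motifs, `[[`, numeric(1), "llr")
    ord <- order(-llrs)
    motifs <- motifs[ord][llrs[ord] >= llr_min]
    ranked <- tibble(
      rank = seq_along(motifs),
      width = vapply(motifs, `[[`, numeric(1), "width"),
      consensus = vapply(motifs, `[[`, character(1), "consensus"),
      llr = vapply(motifs, `[[`, numeric(1), "llr"),
      nsites = vapply(motifs, `[[`, numeric(1), "nsites"),
      gamma = vapply(motifs, `[[`, numeric(1), "gamma"))
    structure(list(motifs = motifs, background = bg, ranked = ranked),
              class = "fr_zoops")
  })
}

#' @method tidy fr_zoops
#' @export
tidy.fr_zoops <- function(x, ...) x$ranked

#' @method glance fr_zoops
#' @export
glance.fr_zoops <- function(x, ...) {
  if (nrow(x$ranked) == 0) return(tibble(n_motifs = 0L))
  dplyr::bind_cols(tibble(n_motifs = nrow(x$ranked)), x$ranked[1, -1])
}

#' @export
print.fr_zoops <- function(x, ...) {
  cat(sprintf("ZOOPS-EM discovery: %d motif(s)\n", length(x$motifs)))
  print(x$ranked)
  invisible(x)
}

#' Convert a discovered motif to an `fr_pwm`
#'
#' @param zoops `fr_zoops` result.
#' @param rank Which ranked motif to extract (default 1).
#' @return `fr_pwm` with the discovery background.
#' @export
zoops_pwm <- function(zoops, rank = 1) {
  m <- zoops$motifs[[rank]]
  new_pwm(m$probs, zoops$background,
          motif_id = paste0("zoops_", m$consensus), pseudocount = 0.25)
}

#' Write discovered motifs as a minimal MEME-format text block
#'
#' @param zoops `fr_zoops` result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_meme <- function(zoops, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               sprintf("Background letter frequencies (from input):"),
               paste(sprintf("%s %.5f", DNA4, zoops$background),
                     collapse = " "), ""), con)
  for (m in zoops$motifs) {
    writeLines(sprintf("MOTIF %s", m$consensus), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %.1f",
      m$width, m$nsites), con)
    utils::write.table(format(m$probs, digits = 6), con,
                       row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    writeLines("", con)
  }
  invisible(path)
}
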