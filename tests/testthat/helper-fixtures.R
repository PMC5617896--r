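# Shared fixture builders and independent oracles used across test files.

random_dna <- function(n, len, seed = NULL,
                       probs = c(0.25, 0.25, 0.25, 0.25)) {
  gen <- function() {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                   prob = probs), collapse = "")
    }, character(1))
  }
  s <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  setNames(s, paste0("seq", seq_len(n)))
}

# Independent IUPAC scanner: per-position set membership, no regex, no
# shared code with the package implementation.
oracle_iupac_scan <- function(seqs, sets) {
  w <- length(sets)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc_sets <- lapply(rev(sets), function(s) unname(comp[s]))
  hits <- list()
  for (id in names(seqs)) {
    chars <- strsplit(seqs[[id]], "")[[1]]
    L <- length(chars)
    for (st in seq_len(max(L - w + 1, 0))) {
      win <- chars[st:(st + w - 1)]
      if (all(mapply(function(ch, set) ch %in% set, win, sets))) {
        hits[[length(hits) + 1]] <-
          data.frame(seq_id = id, strand = "+", start = st)
      }
      if (all(mapply(function(ch, set) ch %in% set, win, rc_sets))) {
        hits[[length(hits) + 1]] <-
          data.frame(seq_id = id, strand = "-", start = st)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(seq_id = character(), strand = character(),
                      start = integer()))
  }
  do.call(rbind, hits)
}

# Independent DNF machinery for the classifier oracle: candidate clauses
# are non-empty subsets of {G, A, R}; a candidate DNF is any subset of
# them. Evaluation by set inclusion only.
oracle_all_clauses <- function() {
  tf <- c("G", "A", "R")
  unlist(lapply(1:3, function(k) combn(tf, k, simplify = FALSE)),
         recursive = FALSE)
}

oracle_eval_clauses <- function(clauses, deleted) {
  any(vapply(clauses, function(cl) all(cl %in% deleted), logical(1)))
}

# All 7 mutant deletion sets, in the package's fixed genotype order.
oracle_mutant_sets <- function() {
  list(G = "G", A = "A", R = "R", AG = c("A", "G"), AR = c("A", "R"),
       GR = c("G", "R"), AGR = c("A", "G", "R"))
}

# Hypergeometric two-sided Fisher p by direct summation (oracle).
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Naive O(n^3) complete-linkage oracle, independent bookkeeping: clusters
# as index sets; inter-cluster distance = max pairwise Euclidean.
oracle_complete_linkage_heights <- function(mat) {
  d <- as.matrix(dist(mat))
  clusters <- lapply(seq_len(nrow(mat)), identity)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        dd <- max(d[clusters[[i]], clusters[[j]]])
        if (dd < best) { best <- dd; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  sort(heights)
}

small_design <- function(replicates = 2, timepoints = "2h") {
  build_design(replicates = replicates, timepoints = timepoints)
}
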