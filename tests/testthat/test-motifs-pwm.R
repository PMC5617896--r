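test_that("PWM constructors validate and a width-1 tail is exact", {
  probs <- matrix(c(0.97, 0.01, 0.01, 0.01), 1, 4)
  pw <- new_pwm(probs)
  dist <- facreg:::pwm_score_dist(pw)
  # p of the maximal score = background probability of the best letter
  max_int <- round(max(pw$logodds) / dist$granularity)
  expect_equal(facreg:::pwm_tail_p(dist, max_int), 0.25, tolerance = 1e-12)
  expect_error(new_pwm(matrix(c(0.5, 0.5, 0.5, 0.5), 1, 4)),
               "probability")
  s <- pwm_from_sites(c("ACG", "ACG", "ACT"))
  expect_equal(dim(s$probs), c(3L, 4L))
  expect_equal(rowSums(s$probs), rep(1, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("DP p-values equal exhaustive enumeration for small widths", {
  enumerate_tail <- function(pw, granularity = 1e-3) {
    w <- pw$width
    S <- round(pw$logodds / granularity)
    bg <- pw$background
    grids <- rep(list(1:4), w)
    all_windows <- as.matrix(expand.grid(grids))
    scores <- integer(nrow(all_windows))
    probs <- rep(1, nrow(all_windows))
    for (k in seq_len(w)) {
      scores <- scores + S[k, all_windows[, k]]
      probs <- probs * bg[all_windows[, k]]
    }
    function(int_score) sum(probs[scores >= int_score])
  }
  for (cfg in list(
    list(w = 2, seed = 81, bg = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)),
    list(w = 7, seed = 82, bg = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)))) {
    probs <- withr::with_seed(cfg$seed, {
      m <- matrix(rgamma(cfg$w * 4, 1), cfg$w, 4)
      m / rowSums(m)
    })
    pw <- new_pwm(probs, background = cfg$bg)
    dist <- facreg:::pwm_score_dist(pw)
    tail_oracle <- enumerate_tail(pw)
    test_scores <- round(seq(dist$min_int, dist$max_int, length.out = 25))
    for (s in test_scores) {
      expect_equal(facreg:::pwm_tail_p(dist, s), tail_oracle(s),
                   tolerance = 1e-12)
    }
  }
})

test_that("PWM scanning finds planted informative sites on both strands", {
  # sharp PWM for TGAGGGG-like site
  site <- "TGAGGGG"
  sites <- c(rep(site, 18), "TGCGGGG", "TGATGGG")
  pw <- pwm_from_sites(sites, motif_id = "rha")
  seq_fwd <- paste0(strrep("ACTT", 30), site, strrep("CAGT", 30))
  seq_rev <- paste0(strrep("ACTT", 30), revcomp(site), strrep("CAGT", 30))
  h <- pwm_scan(c(f = seq_fwd, r = seq_rev), pw, p_threshold = 1e-4)
  expect_true(any(h$seq_id == "f" & h$strand == "+" & h$match == site))
  expect_true(any(h$seq_id == "r" & h$strand == "-" & h$match == site))
  expect_true(all(h$p < 1e-4))
  # windows containing N are skipped, not errors
  h2 <- pwm_scan(c(x = paste0(strrep("A", 20), "TGANGGG",
                              strrep("A", 20))), pw)
  expect_false(any(h2$match == "TGANGGG"))
  expect_error(
    pwm_scan(c(x = "ACGTACGT"),
             new_pwm(matrix(0.25, 2, 4),
                     background = c(A = 0.5, C = 0.5, G = 0, T = 0))),
    "Background")
})

test_that("strand-symmetric background gives mirror-image hit sets", {
  pw <- pwm_from_sites(c(rep("TGAGGGG", 9), "TGAGGGT"))
  seqs <- random_dna(30, 200, seed = 83)
  fwd <- pwm_scan(seqs, pw, p_threshold = 1e-3)
  rc <- setNames(revcomp(seqs), names(seqs))
  rev <- pwm_scan(rc, pw, p_threshold = 1e-3)
  key <- function(df, L, w) {
    sort(paste(df$seq_id, df$strand, df$start, signif(df$p, 10)))
  }
  mapped <- sort(paste(rev$seq_id, ifelse(rev$strand == "+", "-", "+"),
                       200 - (rev$start + pw$width - 1) + 1,
                       signif(rev$p, 10)))
  expect_equal(key(fwd), mapped)
})
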