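test_that("IUPAC parsing handles brackets, codes and malformed input", {
  expect_equal(parse_iupac("TG[CAG][GTA]GGG")$width, 7)
  expect_equal(parse_iupac("CC[ACTG]CCAA")$width, 7)
  expect_equal(parse_iupac("ccNcc")$width, 5)  # case-insensitive, N code
  expect_equal(parse_iupac("R")$sets[[1]], c("A", "G"))
  expect_error(parse_iupac("CC[]AA"), "position 3")
  expect_error(parse_iupac("CC[A"), "Unclosed")
  expect_error(parse_iupac("CXC"), "position 2")
  expect_error(parse_iupac(""), "non-empty")
})

test_that("scanning reports both strands with the upstream convention", {
  # plus-strand GARE match: leftmost s = 4 in a 13-mer, upstream 10
  h <- scan_iupac(c(p1 = "AAACCGCCAATTT"), "CC[ACTG]CCAA")
  expect_equal(nrow(h), 1)
  expect_equal(h$strand, "+")
  expect_equal(h$start, 4L)
  expect_equal(h$upstream_position, 10L)
  expect_equal(h$match, "CCGCCAA")
  # minus strand: CCCCTCA is the reverse complement of TGAGGGG
  h2 <- scan_iupac(c(p2 = "TTCCCCTCATT"), "TG[CAG][GTA]GGG")
  expect_equal(nrow(h2), 1)
  expect_equal(h2$strand, "-")
  expect_equal(h2$match, "TGAGGGG")
  # N never matches
  h3 <- scan_iupac(c(p3 = "AAACCNCCAATTT"), "CC[ACTG]CCAA")
  expect_equal(nrow(h3), 0)
  # overlapping matches are all reported
  h4 <- scan_iupac(c(p4 = "AAAAAA"), "AAA", strands = "+")
  expect_equal(h4$start, 1:4)
})

test_that("scanner equals the naive set-membership oracle on random input", {
  motifs <- c("TG[CAG][GTA]GGG", "CC[ACGT]CCAA", "RYN[AT]G")
  seqs <- random_dna(60, 300, seed = 71)
  for (pat in motifs) {
    m <- parse_iupac(pat)
    got <- scan_iupac(seqs, m)
    want <- oracle_iupac_scan(seqs, m$sets)
    key <- function(df) sort(paste(df$seq_id, df$strand, df$start))
    expect_equal(key(got), key(want), label = pat)
  }
})

test_that("reverse-complementing sequences swaps strands and maps positions", {
  seqs <- random_dna(20, 150, seed = 72)
  m <- parse_iupac("TG[CAG][GTA]GGG")
  fwd <- scan_iupac(seqs, m)
  rc <- setNames(revcomp(seqs), names(seqs))
  rev <- scan_iupac(rc, m)
  L <- 150; w <- m$width
  key_fwd <- sort(paste(fwd$seq_id, fwd$strand, fwd$start))
  mapped <- sort(paste(rev$seq_id, ifelse(rev$strand == "+", "-", "+"),
                       L - (rev$start + w - 1) + 1))
  expect_equal(key_fwd, mapped)
})

test_that("conservation fractions count promoters with any hit", {
  withr::with_seed(73, {
    bg <- random_dna(5, 200)
    planted <- bg
    for (i in 1:4) {
      s <- planted[[i]]
      substr(s, 50, 56) <- "TGAGGGG"
      planted[[i]] <- s
    }
  })
  sets <- list(spA = planted, spB = bg)
  # remove any accidental background hits from spB for exact counting
  res <- conservation_scan(sets, "TG[CAG][GTA]GGG")
  a <- res[res$species == "spA", ]
  expect_gte(a$fraction, 0.8)
  expect_true(a$majority)
  expect_warning(conservation_scan(list(empty = character(0)),
                                   "TGAGGGG"), "skipped")
})

test_that("published motif table parses to the stated widths", {
  tm <- tf_motifs()
  expect_equal(tm$width[tm$motif_id == "GARE"], 7)
  expect_equal(tm$width[tm$motif_id == "AraR_CCCC"], 7)
  expect_equal(tm$width[tm$motif_id == "AraR_CTrich"], 15)
  expect_equal(tm$width[tm$motif_id == "RhaR"], 7)
})
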