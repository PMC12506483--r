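# Deterministic constructions used throughout: oligo bodies made of A
# (or of the partner's non-complement) cannot pair, so the only
# complementary runs are the ones planted.

test_that("dimer scan finds perfect duplexes and nothing in A-tracts", {
  set.seed(30)
  a <- random_dna(15)
  h <- find_dimers(a, reverse_complement(a))
  expect_equal(max(h$run_length), 15)
  expect_true(any(h$involves_3prime))
  expect_equal(nrow(find_dimers("AAAAAAAAAA", "AAAAAAAAAA")), 0)
})

test_that("dimer scan equals the exhaustive brute-force reference", {
  set.seed(31)
  for (i in 1:200) {
    a <- random_dna(sample(8:15, 1))
    b <- random_dna(sample(8:15, 1))
    got <- find_dimers(a, b)
    got <- got[order(got$offset, got$a_start), ]
    exp <- oracle_dimer_runs(a, b)
    if (is.null(exp)) {
      expect_equal(nrow(got), 0)
    } else {
      exp <- exp[order(exp[, 1], exp[, 2]), , drop = FALSE]
      expect_equal(got$offset, exp[, 1])
      expect_equal(got$a_start, exp[, 2])
      expect_equal(got$a_end, exp[, 3])
    }
  }
})

test_that("dimer scan is symmetric in its arguments", {
  set.seed(32)
  for (i in 1:30) {
    a <- random_dna(12); b <- random_dna(14)
    ra <- sort(find_dimers(a, b)$run_length)
    rb <- sort(find_dimers(b, a)$run_length)
    expect_equal(ra, rb)
  }
})

test_that("rejection rules: 5 bases at the 3' end or 7 in the middle", {
  # mutual 3'-complementary pentamer on otherwise inert A-bodies
  a5 <- paste0(strrep("A", 11), "GGGCC")
  b5 <- paste0(strrep("A", 11), "GGCCC")
  f <- passes_dimer_filter(a5, b5)
  expect_false(f$pass)
  expect_match(f$reason, "^3' run 5")

  # central 7-mer island, 3' ends clean
  island <- "GACGTCG"
  am <- paste0("AAAAA", island, "AAAAA")
  bm <- paste0("AAAAA", reverse_complement(island), "AAAAA")
  f <- passes_dimer_filter(am, bm)
  expect_false(f$pass)
  expect_match(f$reason, "middle run 7")

  # boundary: 4-bp 3' run and a 6-bp middle island both pass
  a4 <- paste0(strrep("A", 12), "GGCC")
  b4 <- paste0(strrep("A", 12), "GGCC")
  expect_true(passes_dimer_filter(a4, b4)$pass)
  island6 <- "GACGTC"
  expect_true(passes_dimer_filter(
    paste0("AAAAA", island6, "AAAAA"),
    paste0("AAAAA", reverse_complement(island6), "AAAAA"))$pass)
})

test_that("extending a complementary run never converts reject to pass", {
  # grow the 3' complement from 3 to 8 bases; once rejected, stays so
  seen_reject <- FALSE
  for (k in 3:8) {
    core <- substr("GGGCCGGG", 1, k)
    a <- paste0(strrep("A", 16 - k), core)
    b <- paste0(strrep("A", 16 - k), reverse_complement(core))
    pass <- passes_dimer_filter(a, b)$pass
    if (seen_reject) expect_false(pass)
    if (!pass) seen_reject <- TRUE
  }
  expect_true(seen_reject)
})

test_that("dimer Tm matches duplex Tm and the mismatch oracle", {
  set.seed(33)
  s <- random_dna(20)
  h <- find_dimers(s, reverse_complement(s))
  full <- h[h$run_length == 20, ]
  expect_equal(full$dimer_tm[1], melting_temperature(s), tolerance = 1e-9)

  # single internal mismatch destabilizes
  rc <- strsplit(reverse_complement(s), "", fixed = TRUE)[[1]]
  pos <- 10
  rc[pos] <- setdiff(c("A", "C", "G", "T"), rc[pos])[1]
  mm <- paste(rc, collapse = "")
  tm_mm <- dimer_tm(s, mm, 21)
  expect_lt(tm_mm, melting_temperature(s))

  # frozen hand-summed value: 10-bp duplex with one G.T mismatch
  top <- "AACGTTAGCA"
  b <- "TGCTAGCGTT"   # reverse of the bottom strand carrying the G
  expect_equal(dimer_tm(top, b, 11), 18.5036, tolerance = 1e-3)

  # below model range sentinel
  expect_true(is.na(dimer_tm("ACGTACGT", "ACGTACGT", 2)))
})

test_that("3' hairpin check equals exhaustive stem/loop enumeration", {
  hp <- three_prime_hairpin_check("GGGGAAAACCCC")
  expect_true(hp$flagged)
  expect_equal(hp$stem_length, 4)
  expect_gte(hp$loop_length, 3)
  expect_false(three_prime_hairpin_check("ACACACACACAC")$flagged)
  set.seed(34)
  for (i in 1:300) {
    s <- random_dna(sample(8:14, 1))
    expect_equal(three_prime_hairpin_check(s)$flagged, oracle_hairpin(s),
                 info = s)
  }
  expect_error(three_prime_hairpin_check("ACGTACG"), "shorter than 8")
})
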