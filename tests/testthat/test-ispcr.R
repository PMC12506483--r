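test_that("seed index lookups tolerate one mismatch", {
  idx <- build_seed_index(strrep("A", 50))
  expect_equal(length(lookup_seed(idx, strrep("A", 12))), 39)
  set.seed(40)
  tpl <- random_dna(500)
  idx <- build_seed_index(tpl)
  w <- substr(tpl, 101, 112)
  expect_true(101 %in% lookup_seed(idx, w))
  # one mismatch in the query still hits
  wm <- w
  substr(wm, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(w, 5, 5))[1]
  expect_true(101 %in% lookup_seed(idx, wm))
  # a word absent beyond one mismatch returns nothing
  expect_equal(length(lookup_seed(build_seed_index(strrep("A", 30)),
                                  "GGGGGGGGGGGG")), 0)
})

test_that("binding sites equal the exhaustive scan under default policy", {
  set.seed(41)
  for (i in 1:60) {
    tpl <- random_dna(300)
    pr <- substr(tpl, 50, 69)
    substr(pr, sample(1:18, 1), sample(1:18, 1)) <-
      sample(c("A", "C", "G", "T"), 1)
    got <- find_binding_sites(c(p = pr), tpl)
    exp <- oracle_sites(pr, tpl)
    expect_equal(paste(got$strand, got$start, got$end,
                       got$total_mismatches),
                 paste(exp$strand, exp$start, exp$end, exp$mm))
  }
})

test_that("policy knobs act on 3' mismatches, terminal bases and tails", {
  set.seed(42)
  tpl <- random_dna(400)
  pr <- substr(tpl, 201, 220)
  # exact primer: one site, zero mismatches, correct 3' coordinate
  s <- find_binding_sites(c(p = pr), tpl)
  expect_equal(nrow(s), 1)
  expect_equal(s$total_mismatches, 0)
  expect_equal(s$three_prime_pos, 220)
  # mismatch 8 nt from the 3' end: tolerated by the seed
  p8 <- pr
  substr(p8, 13, 13) <- setdiff(c("A", "C", "G", "T"),
                                substr(pr, 13, 13))[1]
  expect_equal(nrow(find_binding_sites(c(p = p8), tpl)), 1)
  # terminal-base mismatch killed by terminal2_must_match, revived off
  pt <- pr
  substr(pt, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                substr(pr, 20, 20))[1]
  expect_equal(nrow(find_binding_sites(c(p = pt), tpl)), 0)
  s2 <- find_binding_sites(c(p = pt), tpl,
                           ispcr_policy(terminal2_must_match = FALSE))
  expect_equal(nrow(s2), 1)
  expect_true(s2$terminal2_mismatch)
  # 5' tail excluded from mismatch counting
  tailed <- paste0("GGGGGGGG", substr(tpl, 1, 16))
  st <- find_binding_sites(c(p = tailed), tpl)
  near <- st[st$strand == "+" & st$start == 1, ]
  expect_equal(nrow(near), 1)
  expect_equal(near$tail_len, 8)
  expect_equal(near$total_mismatches, 0)
})

test_that("amplicon prediction closes on designed products and wraps circles", {
  set.seed(43)
  tpl <- random_dna(600)
  fwd <- substr(tpl, 101, 120)
  rev <- reverse_complement(substr(tpl, 281, 300))
  r <- in_silico_pcr(c(F = fwd, R = rev), tpl, size = c(50, 1000))
  expect_equal(nrow(r$amplicons), 1)
  expect_equal(r$amplicons$start, 101)
  expect_equal(r$amplicons$end, 300)
  expect_equal(r$amplicons$length, 200)
  expect_equal(r$amplicons$sequence, substr(tpl, 101, 300))

  ct <- dna_sequence(tpl, circular = TRUE)
  fw2 <- substr(tpl, 501, 520)
  rv2 <- reverse_complement(substr(tpl, 81, 100))
  rc <- in_silico_pcr(c(F = fw2, R = rv2), ct, size = c(50, 1000))
  wrap <- rc$amplicons[rc$amplicons$mode == "circular-wrapped", ]
  expect_equal(nrow(wrap), 1)
  expect_equal(wrap$length, (600 - 501 + 1) + 100)
  expect_equal(wrap$sequence,
               paste0(substr(tpl, 501, 600), substr(tpl, 1, 100)))

  # combinatorial pairing: two forward sites, one reverse -> two products
  seg <- substr(tpl, 101, 120)
  tpl2 <- paste0(substr(tpl, 1, 300), seg, substr(tpl, 321, 600))
  rv3 <- reverse_complement(substr(tpl2, 401, 420))
  r3 <- in_silico_pcr(c(F = seg, R = rv3), tpl2, size = c(50, 1000))
  expect_equal(nrow(r3$amplicons), 2)
})

test_that("strand symmetry: sites mirror on the reverse complement", {
  set.seed(44)
  tpl <- random_dna(300)
  pr <- substr(tpl, 120, 139)
  s1 <- find_binding_sites(c(p = pr), tpl)
  s2 <- find_binding_sites(c(p = pr), reverse_complement(tpl))
  expect_equal(nrow(s1), nrow(s2))
  expect_equal(sort(300 - s1$end + 1), sort(s2$start))
  expect_equal(sort(s1$strand), sort(chartr("+-", "-+", s2$strand)))
})

test_that("short-oligo screening is capped at three mismatches", {
  set.seed(45)
  tpl <- random_dna(400)
  oligo <- substr(tpl, 201, 222)
  expect_error(screen_short_oligo(oligo, tpl, 4), "not exceed|between")
  expect_error(screen_short_oligo(oligo, tpl, 0), "between")
  hit <- screen_short_oligo(oligo, tpl, 3)
  expect_true(any(hit$start == 201 & hit$total_mismatches == 0))
  # equality with a naive full scan
  for (i in 1:20) {
    t2 <- random_dna(200)
    ol <- substr(t2, 91, 110)
    substr(ol, 5, 5) <- "T"; substr(ol, 15, 15) <- "G"
    got <- screen_short_oligo(ol, t2, 3)
    # naive: Hamming over all positions, both strands
    oc <- strsplit(ol, "", fixed = TRUE)[[1]]
    exp_n <- 0L
    for (sgn in c("+", "-")) {
      tg <- if (sgn == "+") t2 else reverse_complement(t2)
      tc <- strsplit(tg, "", fixed = TRUE)[[1]]
      for (st in 1:(200 - 20 + 1)) {
        if (sum(oc != tc[st:(st + 19)]) <= 3) exp_n <- exp_n + 1L
      }
    }
    expect_equal(nrow(got), exp_n)
  }
})
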