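test_that("candidate filters are replayed exactly by an independent check", {
  set.seed(50)
  tpl <- random_dna(500)
  cns <- design_constraints()
  cands <- generate_candidates(tpl, cns)
  expect_gt(nrow(cands), 0)
  for (i in seq_len(nrow(cands))) {
    sq <- cands$sequence[i]
    # sequence equals the template slice (or its reverse complement)
    slice <- substr(tpl, cands$start[i], cands$end[i])
    expect_equal(sq, if (cands$strand[i] == "+") slice
                     else reverse_complement(slice))
    tm <- melting_temperature(sq)
    expect_true(tm >= cns$tm_range[1] && tm <= cns$tm_range[2])
    gc <- gc_content(sq)
    expect_true(gc >= cns$gc_range[1] && gc <= cns$gc_range[2])
    expect_gte(linguistic_complexity(sq), cns$lc_min)
    expect_true(passes_dimer_filter(sq, sq)$pass)
  }
})

test_that("hopeless templates return empty with per-filter counts", {
  cands <- generate_candidates(strrep("A", 200))
  expect_equal(nrow(cands), 0)
  rej <- attr(cands, "rejections")
  expect_true(sum(rej) > 0)
  expect_identical(attr(cands, "message"), "no primers found")
})

test_that("G-quadruplex windows are flagged and dropped", {
  set.seed(51)
  motif <- "GGGAGGGTGGGAGGGT"
  tpl <- paste0(random_dna(200), motif, random_dna(200))
  cands <- generate_candidates(tpl)
  gq_start <- 201; gq_end <- 200 + nchar(motif)
  overlaps <- cands$start <= gq_end & cands$end >= gq_start
  expect_false(any(overlaps))
  expect_gt(attr(cands, "rejections")[["gquad"]], 0)
})

test_that("designed pairs satisfy all pair constraints (validator oracle)", {
  set.seed(52)
  tpl <- random_dna(400)
  pp <- design_pairs(tpl)
  expect_gt(nrow(pp), 0)
  for (i in seq_len(nrow(pp))) {
    expect_true(passes_dimer_filter(pp$f_sequence[i], pp$r_sequence[i])$pass)
    expect_lte(abs(pp$f_tm[i] - pp$r_tm[i]), 3)
    expect_true(pp$product_len[i] >= 100 && pp$product_len[i] <= 300)
    expect_equal(pp$product_len[i], pp$r_end[i] - pp$f_start[i] + 1)
  }
  # returned pairs are mutually distinct
  key <- paste(pp$f_name, pp$r_name)
  expect_false(any(duplicated(key)))
  # ranking is deterministic and sorted
  expect_true(all(diff(pp$rank_score) <= 1e-12))
  pp2 <- design_pairs(tpl)
  expect_equal(as.data.frame(pp), as.data.frame(pp2))
})

test_that("every designed pair closes through in silico PCR", {
  set.seed(53)
  tpl <- random_dna(400)
  pp <- design_pairs(tpl, max_pairs = 5)
  for (i in seq_len(nrow(pp))) {
    r <- in_silico_pcr(c(F = pp$f_sequence[i], R = pp$r_sequence[i]),
                       tpl, size = c(50, 1000))
    expect_equal(nrow(r$amplicons), 1)
    expect_equal(r$amplicons$start, pp$f_start[i])
    expect_equal(r$amplicons$end, pp$r_end[i])
    expect_equal(r$amplicons$total_mismatches, 0)
  }
})

test_that("inverse mode on circular templates spans the origin", {
  set.seed(54)
  tpl <- dna_sequence(random_dna(600), circular = TRUE)
  cns <- design_constraints(mode = "inverse", product_size = c(150, 450))
  pp <- design_pairs(tpl, cns)
  expect_gt(nrow(pp), 0)
  for (i in seq_len(min(nrow(pp), 5))) {
    expect_gt(pp$f_start[i], pp$r_end[i])
    expect_equal(pp$product_len[i],
                 (600 - pp$f_start[i] + 1) + pp$r_end[i])
    r <- in_silico_pcr(c(F = pp$f_sequence[i], R = pp$r_sequence[i]),
                       tpl, size = c(50, 1000))
    wrap <- r$amplicons[r$amplicons$mode == "circular-wrapped", ]
    expect_equal(nrow(wrap), 1)
    expect_equal(wrap$length, pp$product_len[i])
  }
  expect_error(design_pairs(random_dna(600), cns), "circular")
})

test_that("bisulfite mode designs on the converted strand", {
  set.seed(55)
  tpl <- random_dna(500, gc = 55)
  cns <- design_constraints(mode = "bisulfite", tm_range = c(55, 62),
                            gc_range = c(20, 60))
  pp <- design_pairs(tpl, cns)
  expect_gt(nrow(pp), 0)
  conv <- bisulfite_convert(tpl, "plus")
  cpg_c <- which(strsplit(conv, "", fixed = TRUE)[[1]] == "C")
  for (i in seq_len(nrow(pp))) {
    # forward primers: C only at preserved CpG positions, never at the 3' end
    fc <- which(strsplit(pp$f_sequence[i], "", fixed = TRUE)[[1]] == "C")
    expect_true(all((pp$f_start[i] + fc - 1) %in% cpg_c))
    expect_false(pp$f_end[i] %in% cpg_c)
    # closure on the converted template
    r <- in_silico_pcr(c(F = pp$f_sequence[i], R = pp$r_sequence[i]),
                       conv, size = c(50, 1000))
    expect_true(any(r$amplicons$start == pp$f_start[i] &
                      r$amplicons$end == pp$r_end[i] &
                      r$amplicons$total_mismatches == 0))
  }
})

test_that("bracket regions restrict primer placement", {
  set.seed(56)
  tpl <- random_dna(500)
  regions <- data.frame(start = c(1, 401), end = c(120, 500),
                        role = c("forward-zone", "reverse-zone"))
  pp <- design_pairs(tpl, design_constraints(product_size = c(250, 500)),
                     regions = regions)
  if (nrow(pp)) {
    expect_true(all(pp$f_start >= 1 & pp$f_end <= 120))
    expect_true(all(pp$r_start >= 401 & pp$r_end <= 500))
  } else {
    succeed("no pair in zones for this seed; placement constraint holds")
  }
})

test_that("TaqMan and MGB probes satisfy their invariant sets", {
  set.seed(57)
  n_done <- 0
  for (i in 1:6) {
    tpl <- random_dna(400)
    pp <- design_pairs(tpl, max_pairs = 3)
    if (!nrow(pp)) next
    pr <- tryCatch(design_probe(tpl, pp[1, ], "TaqMan"),
                   error = function(e) NULL)
    if (is.null(pr)) next
    n_done <- n_done + 1
    expect_true(pr$length >= 15 && pr$length <= 30)
    expect_true(pr$gc >= 45 && pr$gc <= 65)
    expect_true(pr$tm >= 68 && pr$tm <= 72)
    expect_false(startsWith(pr$sequence, "G"))
    expect_true(pr$start > pp$f_end[1] && pr$end < pp$r_start[1])
    expect_true(passes_dimer_filter(pr$sequence, pp$f_sequence[1])$pass)
    expect_true(passes_dimer_filter(pr$sequence, pp$r_sequence[1])$pass)
    mgb <- tryCatch(design_probe(tpl, pp[1, ], "MGB"),
                    error = function(e) NULL)
    if (!is.null(mgb)) {
      expect_true(mgb$length >= 13 && mgb$length <= 30)
      expect_lte(abs(mgb$tm - mean(c(pp$f_tm[1], pp$r_tm[1]))), 1)
      expect_false(startsWith(mgb$sequence, "G"))
    }
  }
  expect_gt(n_done, 2)
  # region too short raises a structured error
  set.seed(58)
  tpl <- random_dna(400)
  pp <- design_pairs(tpl, max_pairs = 1)
  fake <- pp[1, ]
  fake$r_start <- fake$f_end + 10
  expect_error(design_probe(tpl, fake, "TaqMan"), "too short")
})
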