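test_that("LAMP sets honor geometry, fusion-primer structure and dimers", {
  set.seed(60)
  tpl <- random_dna(1000)
  sets <- design_lamp(tpl, max_sets = 3)
  expect_gt(nrow(sets), 0)
  res <- attr(sets, "template_used")
  for (i in seq_len(nrow(sets))) {
    s <- sets[i, ]
    # region ordering and disjointness
    ord <- c(s$f3_start, s$f3_end, s$f2_start, s$f2_end, s$f1_start,
             s$f1_end, s$b1_start, s$b1_end, s$b2_start, s$b2_end,
             s$b3_start, s$b3_end)
    expect_true(all(diff(ord) >= 0))
    # FIP = revcomp(F1 region) + F2 region, character for character
    expect_equal(s$fip_seq,
                 paste0(reverse_complement(substr(res, s$f1_start,
                                                  s$f1_end)),
                        substr(res, s$f2_start, s$f2_end)))
    # BIP mirrored: B1 region + revcomp(B2 region)
    expect_equal(s$bip_seq,
                 paste0(substr(res, s$b1_start, s$b1_end),
                        reverse_complement(substr(res, s$b2_start,
                                                  s$b2_end))))
    expect_equal(s$b3_seq,
                 reverse_complement(substr(res, s$b3_start, s$b3_end)))
    # F2-B2 span within the configured bounds
    expect_equal(s$amplicon_f2b2, s$b2_end - s$f2_start + 1)
    expect_true(s$amplicon_f2b2 >= 120 && s$amplicon_f2b2 <= 300)
    # spacing: loop-forming gaps and outer-primer gaps
    expect_true(s$f1_start - s$f2_end - 1 >= 20 &&
                  s$f1_start - s$f2_end - 1 <= 60)
    expect_true(s$b2_start - s$b1_end - 1 >= 20 &&
                  s$b2_start - s$b1_end - 1 <= 60)
    expect_lte(s$f2_start - s$f3_end - 1, 20)
    expect_lte(s$b3_start - s$b2_end - 1, 20)
    # no intra-set dimers among the core four
    oligos <- c(F3 = s$f3_seq, FIP = s$fip_seq, BIP = s$bip_seq,
                B3 = s$b3_seq)
    expect_equal(nrow(audit_dimer_compatibility(oligos)), 0)
    if (s$loops) {
      # loop primers live inside their spacers: LF minus strand, LB plus
      expect_true(s$lf_start > s$f2_end && s$lf_end < s$f1_start)
      expect_true(s$lb_start > s$b1_end && s$lb_end < s$b2_start)
      expect_equal(s$lf_seq,
                   reverse_complement(substr(res, s$lf_start, s$lf_end)))
      expect_equal(s$lb_seq, substr(res, s$lb_start, s$lb_end))
      # with loops the set references 8 distinct disjoint regions
      starts <- c(s$f3_start, s$f2_start, s$lf_start, s$f1_start,
                  s$b1_start, s$lb_start, s$b2_start, s$b3_start)
      ends <- c(s$f3_end, s$f2_end, s$lf_end, s$f1_end, s$b1_end,
                s$lb_end, s$b2_end, s$b3_end)
      o <- order(starts)
      expect_true(all(starts[o][-1] > ends[o][-8]))
      for (lp in c(s$lf_seq, s$lb_seq)) {
        for (co in oligos) {
          expect_true(passes_dimer_filter(lp, co)$pass)
        }
      }
    }
  }
})

test_that("outer primers close through in silico PCR over the full set", {
  set.seed(60)
  tpl <- random_dna(1000)
  sets <- design_lamp(tpl, with_loops = FALSE, max_sets = 1)
  s <- sets[1, ]
  res <- attr(sets, "template_used")
  r <- in_silico_pcr(c(F3 = s$f3_seq, B3 = s$b3_seq), res,
                     size = c(100, 1000))
  expect_equal(nrow(r$amplicons), 1)
  expect_equal(r$amplicons$start, s$f3_start)
  expect_equal(r$amplicons$end, s$b3_end)
  # the outer product contains every inner region
  expect_true(r$amplicons$start < s$f2_start &&
                r$amplicons$end > s$b2_end)
})

test_that("infeasible geometry fails with a structured shortfall", {
  set.seed(61)
  expect_error(design_lamp(random_dna(150)), "insufficient flanks")
})

test_that("too-small loop spacers are flagged, not fatal", {
  set.seed(62)
  tpl <- random_dna(1000)
  sets <- design_lamp(tpl, with_loops = FALSE, max_sets = 1)
  s <- sets[1, ]
  s$f1_start <- s$f2_end + 6   # artificial 5-nt spacer
  filled <- loop_primer_fill(s, attr(sets, "template_used"))
  expect_false(filled$loops)
  expect_match(filled$loop_note, "LF")
})

test_that("bisulfite LAMP primers carry no unconverted cytosine", {
  set.seed(64)
  tpl <- random_dna(1200, gc = 55)
  cfg <- lamp_config(tm_core = c(52, 58), tm_f1c = c(56, 62),
                     tm_loop = c(54, 60), gc_range = c(10, 60),
                     lc_min = 55)
  sets <- design_lamp(tpl, cfg, with_loops = FALSE, bisulfite = "plus",
                      max_sets = 1)
  s <- sets[1, ]
  conv <- attr(sets, "template_used")
  expect_equal(conv, bisulfite_convert(tpl, "plus"))
  cpg_c <- which(strsplit(conv, "", fixed = TRUE)[[1]] == "C")
  # plus-strand-annealing parts (F3, F2) contain C only at CpG sites
  f3_c <- which(strsplit(s$f3_seq, "", fixed = TRUE)[[1]] == "C")
  expect_true(all((s$f3_start + f3_c - 1) %in% cpg_c))
  f2_part <- substr(conv, s$f2_start, s$f2_end)
  f2_c <- which(strsplit(f2_part, "", fixed = TRUE)[[1]] == "C")
  expect_true(all((s$f2_start + f2_c - 1) %in% cpg_c))
})
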