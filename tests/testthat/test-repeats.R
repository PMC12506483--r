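test_that("k-mer frequency profiles count planted copies", {
  set.seed(90)
  bg <- random_dna(2000)
  prof <- kmer_frequency_profile(bg, 12)
  expect_true(mean(prof == 1) > 0.99)   # unique background k-mers

  seg <- random_dna(100)
  tpl <- paste0(random_dna(500), seg, random_dna(500), seg,
                random_dna(500))
  prof2 <- kmer_frequency_profile(tpl, 12)
  inside <- c(501:(501 + 100 - 12), 1101:(1101 + 100 - 12))
  expect_true(all(prof2[inside] >= 2))

  ms <- paste0(random_dna(300), strrep("AC", 30), random_dna(300))
  prof3 <- kmer_frequency_profile(ms, 12)
  expect_gt(max(prof3[301:340]), 10)
})

test_that("block calling recovers planted boundaries within k", {
  set.seed(91)
  seg <- random_dna(200)
  tpl <- paste0(random_dna(600), seg, random_dna(600), seg,
                random_dna(600))
  truth <- data.frame(start = c(601, 1401), end = c(800, 1600))
  blocks <- call_repeat_blocks(kmer_frequency_profile(tpl, 12), 12)
  expect_equal(nrow(blocks), 2)
  for (i in 1:2) {
    expect_lte(abs(blocks$start[i] - truth$start[i]), 12)
    expect_lte(abs(blocks$end[i] - truth$end[i]), 12)
    expect_gte(blocks$peak_kmer_frequency[i], 2)
  }
  # nothing repeated -> nothing called
  expect_equal(nrow(call_repeat_blocks(
    kmer_frequency_profile(random_dna(1500), 12), 12)), 0)
  # a telomere-like tract is called as one block covering >= 95% of it
  tel <- paste0(random_dna(400), strrep("TTTAGGG", 40), random_dna(400))
  tb <- call_repeat_blocks(kmer_frequency_profile(tel, 12), 12)
  cov <- sum(pmin(tb$end, 400 + 280) - pmax(tb$start, 401) + 1)
  expect_gte(cov / 280, 0.95)
})

test_that("clustering groups homologous blocks with orientation", {
  set.seed(92)
  seg <- random_dna(250)
  tpl <- paste0(random_dna(500), seg, random_dna(500),
                reverse_complement(seg), random_dna(500), seg,
                random_dna(400), random_dna(260), random_dna(200))
  blocks <- data.frame(
    start = c(501, 1251, 2001, 2651),
    end = c(750, 1500, 2250, 2910))
  cl <- cluster_blocks(blocks, tpl, sim_threshold = 0.7)
  # the three seg copies cluster together, the random block apart
  seg_rows <- cl[cl$start %in% c(501, 1251, 2001), ]
  expect_equal(length(unique(seg_rows$cluster)), 1)
  expect_equal(sort(seg_rows$strand), c("+", "+", "-"))
  expect_equal(seg_rows$strand[seg_rows$start == 1251], "-")
  other <- cl[cl$start == 2651, ]
  expect_false(other$cluster == seg_rows$cluster[1])
  # members sorted by length descending within clusters
  expect_true(all(diff(cl$length[cl$cluster == seg_rows$cluster[1]]) <= 0))
})

test_that("masking is exact, idempotent and mode-aware", {
  set.seed(93)
  s <- random_dna(300)
  blocks <- data.frame(start = c(50, 200), end = c(99, 239))
  m <- mask_sequence(s, blocks, "N")
  expect_equal(mask_sequence(s, data.frame(start = integer(0),
                                           end = integer(0))), s)
  expect_equal(mask_sequence(m, blocks, "N"), m)
  expect_equal(sum(strsplit(m, "")[[1]] == "N"), 50 + 40)
  low <- mask_sequence(s, blocks, "lowercase")
  expect_equal(toupper(low), s)
})

test_that("repeat reports round-trip through the tab-delimited file", {
  set.seed(94)
  seg <- random_dna(150)
  tpl <- paste0(random_dna(400), seg, random_dna(400), seg,
                random_dna(400))
  rep <- find_repeats(tpl)
  path <- tempfile(fileext = ".tsv")
  write_repeat_report(rep$clusters, path)
  back <- utils::read.delim(path)
  expect_equal(back$start, rep$clusters$start)
  expect_equal(back$end, rep$clusters$end)
  expect_equal(back$strand, rep$clusters$strand)
  expect_equal(back$sequence, rep$clusters$sequence)
  expect_true(all(c("cluster", "start", "end", "strand", "sequence") %in%
                    names(back)))
})

test_that("recall degrades with divergence but stays high at zero", {
  recall_at <- function(div) {
    ft <- generate_template(fixture_spec(
      4242, 20000, 50,
      list(planted_feature("duplication", 300, 3, divergence = div),
           planted_feature("duplication", 200, 2, divergence = div))))
    rp <- find_repeats(ft$sequence)
    L <- length(ft$sequence)
    cov <- rep(FALSE, L); tru <- rep(FALSE, L)
    for (i in seq_len(nrow(rp$blocks))) {
      cov[rp$blocks$start[i]:rp$blocks$end[i]] <- TRUE
    }
    for (i in seq_len(nrow(ft$truth))) {
      tru[ft$truth$start[i]:ft$truth$end[i]] <- TRUE
    }
    mean(cov[tru])
  }
  r0 <- recall_at(0)
  r10 <- recall_at(0.10)
  expect_gte(r0, 0.95)
  expect_lte(r10, r0)
})
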