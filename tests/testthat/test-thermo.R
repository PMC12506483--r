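test_that("NN melting temperature matches the hand-summed oracle", {
  # frozen values from the independent hand-summed oracle
  expect_equal(melting_temperature("ACGTACGTACGTACGTACGT"), 62.6812,
               tolerance = 1e-4)
  expect_equal(melting_temperature("ATGCATTTGGCCAGTACGTA"), 60.7377,
               tolerance = 1e-4)
  expect_equal(melting_temperature("GGGCCCAAATTTGGGCCC"), 68.1745,
               tolerance = 1e-4)
  set.seed(10)
  for (i in 1:25) {
    s <- random_dna(sample(8:40, 1), gc = sample(30:70, 1))
    expect_equal(melting_temperature(s), oracle_tm(s), tolerance = 0.01)
  }
  # self-complementary duplex takes the symmetry correction and CT term
  sc <- "GAATTCGAATTC"
  expect_equal(melting_temperature(sc), oracle_tm(sc), tolerance = 0.01)
})

test_that("Tm is strand symmetric and monotone in concentration and salt", {
  set.seed(11)
  for (i in 1:20) {
    s <- random_dna(sample(10:30, 1))
    expect_equal(melting_temperature(s),
                 melting_temperature(reverse_complement(s)),
                 tolerance = 1e-9)
  }
  s <- "ATGCATTTGGCCAGTACGTA"
  concs <- c(50, 200, 1000)
  tms <- vapply(concs, function(ct) {
    melting_temperature(s, thermo_conditions(oligo_conc = ct))
  }, numeric(1))
  expect_true(all(diff(tms) > 0))
  salts <- c(10, 50, 150, 500, 1000)
  tms <- vapply(salts, function(na) {
    melting_temperature(s, thermo_conditions(monovalent = na,
                                             divalent_mg = 0, dntp = 0))
  }, numeric(1))
  expect_true(all(diff(tms) > 0))
})

test_that("degenerate-site averaging matches expansion means", {
  set.seed(12)
  for (i in 1:10) {
    s <- random_dna(20)
    pos <- sample(2:19, 1)
    mixed <- s
    substr(mixed, pos, pos) <- "N"
    expansions <- vapply(c("A", "C", "G", "T"), function(b) {
      x <- s
      substr(x, pos, pos) <- b
      melting_temperature(x)
    }, numeric(1))
    expect_equal(melting_temperature(mixed), mean(expansions),
                 tolerance = 0.5)
  }
  expect_error(melting_temperature("ACGTA"), "too short")
  expect_error(melting_temperature("NNNNNNNN"), "all-degenerate")
})

test_that("LNA and inosine apply fixed per-base Tm increments", {
  s <- "ATGCATTTGGCCAGTACGTA"
  lna <- sub("A", "E", s)  # one LNA adenine
  expect_equal(melting_temperature(lna), melting_temperature(s) + 2,
               tolerance = 1e-6)
  ino <- sub("G", "I", s)
  # inosine averages over pairings and adds its destabilization penalty
  expect_lt(melting_temperature(ino), melting_temperature(s))
})

test_that("GC content counts degenerates fractionally and LNA by base", {
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("ATGC"), 50)
  expect_equal(gc_content("ASAT"), 25)  # S = G|C counts 1.0
  expect_equal(gc_content("ANAT"), 12.5)
  expect_equal(gc_content("FJ"), 100)   # locked C, G
  expect_error(gc_content(""), "empty")
})

test_that("extinction coefficients follow the NN tables with averaging", {
  expect_equal(extinction_coefficient("A"), 15400)
  expect_equal(extinction_coefficient("AT"), 22800)
  # a single N averages the four expansions
  set.seed(13)
  s <- random_dna(15)
  pos <- 8
  mixed <- s
  substr(mixed, pos, pos) <- "N"
  expansions <- vapply(c("A", "C", "G", "T"), function(b) {
    x <- s
    substr(x, pos, pos) <- b
    extinction_coefficient(x)
  }, numeric(1))
  expect_equal(extinction_coefficient(mixed), mean(expansions),
               tolerance = 1e-9)
})

test_that("physical quantities and dilution arithmetic are consistent", {
  pq <- physical_quantities("AT")
  expect_equal(pq$mw, 313.21 + 304.20 - 61.96, tolerance = 1e-6)
  expect_equal(pq$nmol_per_od, 1e6 / 22800, tolerance = 1e-9)
  set.seed(14)
  s <- random_dna(20)
  pq <- physical_quantities(s)
  expect_equal(pq$ug_per_od, pq$nmol_per_od * pq$mw / 1000,
               tolerance = 1e-9)

  expect_equal(dilution_volume(10, "nmol", 100), 100)
  # OD route: 1 OD is 1e6/eps nmol; volume follows the nmol rule
  vol_od <- 1 * 1e6 / extinction_coefficient(s) * 1000 / 10
  expect_equal(dilution_volume(1, "OD", 10, seq = s), vol_od)
  mw6000 <- dilution_volume(1, "mg", 100, seq = "AAAAAAAAAAAAAAAAAAA")
  expect_equal(mw6000,
               1e6 / physical_quantities("AAAAAAAAAAAAAAAAAAA")$mw * 10,
               tolerance = 1e-9)
  expect_error(dilution_volume(0, "nmol", 10), "> 0")
})

test_that("annealing temperature behaves like the long-duplex rule", {
  ta100 <- annealing_temperature(60, 61, 100, 50)
  ta1000 <- annealing_temperature(60, 61, 1000, 50)
  expect_lte(ta100, ta1000)   # longer products need hotter annealing
  # plug-in evaluation of the formula, independently recomputed
  na <- (50 + 120 * sqrt(1.5 - 0.8)) / 1000
  tp <- 81.5 + 0.41 * 50 - 675 / 500 + 16.6 * log10(na)
  expect_equal(annealing_temperature(60, 62, 500, 50),
               0.3 * 60 + 0.7 * tp - 14.9, tolerance = 1e-9)
  # never exceeds the product Tm
  for (len in c(60, 100, 400, 2000)) {
    expect_lte(annealing_temperature(72, 72, len, 80),
               81.5 + 0.41 * 80 - 675 / len + 16.6 * log10(na) + 1e-9)
  }
})

test_that("oligo set analysis reports every oligo and every pairing", {
  one <- analyze_oligo_set(c(p1 = "ATGCATTTGGCCAGTACGTA"))
  expect_equal(nrow(one$reports), 1)
  expect_equal(nrow(one$dimers), 1)   # the self check
  set.seed(15)
  trio <- vapply(1:3, function(i) random_dna(20), character(1))
  names(trio) <- paste0("p", 1:3)
  res <- analyze_oligo_set(trio)
  expect_equal(nrow(res$reports), 3)
  expect_equal(nrow(res$dimers), 6)   # 3 self + 3 cross
  expect_true(all(c("tm", "gc", "lc", "epsilon_260", "mw",
                    "nmol_per_od", "ug_per_od") %in%
                    names(res$reports)))
  # a primer plus its reverse complement is a perfect cross-dimer
  pair <- c(p = trio[[1]], q = reverse_complement(trio[[1]]))
  res2 <- analyze_oligo_set(pair)
  cross <- res2$dimers[!res2$dimers$self, ]
  expect_false(cross$pass)
})
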