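test_that("variant notation parses SNPs, InDels and multi-allelic blocks", {
  v <- parse_variant_notation("ACGT[A/G]TTAA")
  expect_equal(v$variant_type, "SNP")
  expect_equal(v$alleles, c("A", "G"))
  expect_equal(v$position, 5)

  v2 <- parse_variant_notation("ACGT[-/AGG]TTAA")
  expect_equal(v2$variant_type, "InDel")
  expect_true("" %in% v2$alleles)

  v3 <- parse_variant_notation("AC[AT/GC/AA/TT]GG")
  expect_equal(v3$variant_type, "MNV")
  expect_length(v3$alleles, 4)

  expect_error(parse_variant_notation("AC[A/G/C/T/N]GG"), "1 to 4")
  expect_error(parse_variant_notation("ACGTTTAA"), "exactly one")
  expect_error(parse_variant_notation("AC[A/G]T[A/C]G"), "exactly one")
  expect_error(parse_variant_notation("AC[A/A]GG"), "distinct")
})

test_that("SNP assays discriminate at the 3' terminal base", {
  set.seed(70)
  raw <- paste0(random_dna(200), "[A/G]", random_dna(200))
  v <- parse_variant_notation(raw)
  a <- design_asp_assay(v, placement = "terminal")
  expect_equal(nrow(a$asps), 2)
  # ASPs share the body and differ exactly at the last base
  s1 <- a$asps$sequence[1]; s2 <- a$asps$sequence[2]
  expect_equal(substr(s1, 1, nchar(s1) - 1), substr(s2, 1, nchar(s2) - 1))
  expect_false(substr(s1, nchar(s1), nchar(s1)) ==
                 substr(s2, nchar(s2), nchar(s2)))
  # discrimination audit through in silico PCR: the matching ASP binds
  # with zero mismatches; the other allele gives no extensible site
  for (i in 1:2) {
    for (j in 1:2) {
      tpl <- allele_template(v, v$alleles[j])
      sites <- find_binding_sites(c(asp = a$asps$sequence[i]), tpl)
      if (i == j) {
        expect_equal(nrow(sites), 1)
        expect_equal(sites$total_mismatches, 0)
      } else {
        expect_equal(nrow(sites), 0)
      }
    }
  }
  # the UP anneals perfectly to every allele and flanks the variant
  for (j in 1:2) {
    tpl <- allele_template(v, v$alleles[j])
    up_sites <- find_binding_sites(c(up = a$up$sequence), tpl)
    expect_true(any(up_sites$total_mismatches == 0))
  }
})

test_that("the UP/ASP product spans the variant for every allele", {
  set.seed(71)
  raw <- paste0(random_dna(180), "[C/T]", random_dna(180))
  v <- parse_variant_notation(raw)
  a <- design_asp_assay(v)
  for (j in seq_along(v$alleles)) {
    tpl <- allele_template(v, v$alleles[j])
    r <- in_silico_pcr(c(asp = a$asps$sequence[j], up = a$up$sequence),
                       tpl, size = c(40, 500))
    hit <- r$amplicons[r$amplicons$total_mismatches == 0, ]
    expect_gte(nrow(hit), 1)
    expect_true(any(hit$start <= v$position & hit$end >= v$position))
    expect_true(any(hit$length == a$product_len[j]))
  }
})

test_that("four-allele assays pass the full joint dimer audit", {
  set.seed(72)
  raw <- paste0(random_dna(200), "[A/C/G/T]", random_dna(200))
  a <- design_asp_assay(parse_variant_notation(raw))
  expect_equal(nrow(a$asps), 4)
  oligos <- c(stats::setNames(a$asps$sequence,
                              paste0("ASP", 1:4)), UP = a$up$sequence)
  expect_equal(nrow(audit_dimer_compatibility(oligos)), 0)
})

test_that("InDel assays shift product length and span the junction", {
  set.seed(73)
  raw <- paste0(random_dna(200), "[-/AGGTC]", random_dna(200))
  v <- parse_variant_notation(raw)
  a <- design_asp_assay(v, side = "forward", placement = "terminal")
  expect_equal(unname(diff(range(a$product_len))), 5)
  ins <- a$asps[a$asps$allele == "AGGTC", ]
  del <- a$asps[a$asps$allele == "-", ]
  # insertion ASP 3'-terminates on the last inserted base
  expect_true(endsWith(ins$sequence, "AGGTC"))
  # deletion ASP crosses the junction into the right flank
  expect_equal(substr(del$sequence, nchar(del$sequence),
                      nchar(del$sequence)),
               substr(v$right_flank, 1, 1))
  expect_equal(nchar(ins$sequence) - nchar(del$sequence), 4)
})

test_that("penultimate placement moves the discriminating base inward", {
  set.seed(74)
  raw <- paste0(random_dna(200), "[A/G]", random_dna(200))
  v <- parse_variant_notation(raw)
  a <- design_asp_assay(v, placement = "penultimate")
  s1 <- a$asps$sequence[1]; s2 <- a$asps$sequence[2]
  n <- nchar(s1)
  expect_equal(substr(s1, n, n), substr(s2, n, n))
  expect_false(substr(s1, n - 1, n - 1) == substr(s2, n - 1, n - 1))
})

test_that("reporter tails extend ASPs without touching annealing logic", {
  set.seed(75)
  raw <- paste0(random_dna(200), "[A/G]", random_dna(200))
  a <- design_asp_assay(parse_variant_notation(raw))
  same <- attach_reporter_tails(a, c("", ""))
  expect_equal(same$asps$tailed_sequence, a$asps$sequence)

  # benign synthetic tails: poly-A cannot pair with anything but poly-T
  tailed <- attach_reporter_tails(a, c("AAAAAAAAAA", "AAAAAAAAAA"))
  expect_equal(nchar(tailed$asps$tailed_sequence),
               nchar(a$asps$sequence) + 10)
  expect_equal(vapply(tailed$asps$sequence, melting_temperature,
                      numeric(1), USE.NAMES = FALSE),
               a$asps$tm)

  # a tail complementary to the UP 3' end is rejected
  bad_tail <- reverse_complement(substr(a$up$sequence,
                                        nchar(a$up$sequence) - 7,
                                        nchar(a$up$sequence)))
  expect_error(attach_reporter_tails(a, c(bad_tail, bad_tail)),
               "dimer violation")
})
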