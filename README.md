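# pcrkit

Primer, probe and assay design for the bench: an R toolkit covering the
oligonucleotide arithmetic and the assay-assembly logic that PCR work
keeps needing in one place. It is written for molecular biologists and
bioinformaticians who design standard, inverse, bisulfite, multiplex and
quantitative-fluorescence (TaqMan/MGB) PCR, LAMP sets, KASP-style
allele-specific genotyping assays, Gibson assembly primers, and tiling
amplicon panels — and who want every designed oligo re-checkable by in
silico PCR and repeat analysis on the same machine, with no web service
involved.

## What it computes

* **Thermodynamics** — nearest-neighbor melting temperature
  `Tm = ΔH°/(ΔS° + R ln Cf) − 273.15` from the unified DNA/DNA
  parameter set with initiation terms, degenerate-base averaging, LNA
  (`E/F/J/L`) and inosine handling, and an Owczarzy-style monovalent
  correction at the sodium-equivalent of the Mg²⁺/dNTP buffer;
  extinction coefficients (NN method), molecular weight, nmol/OD,
  µg/OD, dilution volumes, and the annealing temperature rule
  `Ta = 0.3 Tm_min + 0.7 Tm_product − 14.9`.
* **Linguistic complexity (LC)** — the alphabet-capacity k-mer measure
  `LC = 100 · Σ U_k / Σ min(4^k, L−k+1)`, used as a primer acceptance
  filter (default LC ≥ 75) and, windowed, as a low-complexity masker.
* **Dimer screening** — gapless antiparallel alignment over all
  offsets; a pair is rejected on a complementary run of ≥ 5 bases
  touching a 3′ end or ≥ 7 bases anywhere; duplex Tm with published
  internal-mismatch NN parameters; 3′ hairpin check.
* **Design** — candidate enumeration under Tm/GC/LC/G-quadruplex/
  self-dimer filters with repeat masking, ranked pair assembly, TaqMan
  and MGB probe placement, inverse-PCR (circular) and bisulfite modes.
* **In silico PCR** — 12-mer-seeded, mismatch-tolerant binding-site
  search (3′-end-weighted policy), amplicon prediction on linear and
  circular templates, short-oligo (miRNA/gRNA) screening.
* **Assay builders** — multiplex panels via a scarcity-first
  predesigned-list algorithm; ~1.2 kb tiling panels with 500–1000 bp
  overlaps in alternating pools; LAMP sets (F3/FIP/BIP/B3 + loop
  primers); KASP assays (1–4 alleles, SNP/InDel/MNV/haplotype);
  Gibson junction primers with 20–40 bp overlaps at > 50 °C.
* **Repeats** — de novo repeat identification by a canonical k-mer
  frequency transform, block boundary refinement, length-descending
  greedy clustering by k-mer-vector cosine similarity, masking, and
  tab-delimited reports.
* **Fixtures** — a deterministic synthetic-template generator with
  exact ground truth for benchmarking all of the above.

## Worked example

```r
library(pcrkit)
set.seed(11)
template <- random_dna(400, gc = 50)

pairs <- design_pairs(template)
pairs
#> <primer_pairs> 50 ranked pair(s), mode standard
#>   f_name  r_name  f_tm  r_tm product_len    ta rank_score
#> 1 F36_18 R221_21 61.51 61.40         206 63.35     0.9265
#> 2 F34_18 R222_21 61.31 61.24         209 63.26     0.9259
#> 3 F34_18 R221_21 61.31 61.40         208 63.34     0.9258
#> 4 F45_22 R221_21 61.39 61.40         197 62.89     0.9255
#> 5 F36_18 R221_22 61.51 61.62         207 63.32     0.9226
```

Both primers of the top pair melt within the 60–62 °C window, balanced
to 0.1 °C, and the 206 bp product anneals at 63 °C. A hydrolysis probe
between them:

```r
top <- pairs[1, ]
design_probe(template, top, "TaqMan")[, c("sequence", "tm", "gc", "lc")]
#>                     sequence    tm    gc    lc
#> 1 ACCTCATAGTTGCTACCCTCGGTCGT 70.44 53.85 92.13
```

70.4 °C is ~9 °C above the primers, GC and complexity are in range, and
the 5′ base is not G. Closing the loop through in silico PCR finds
exactly the designed product, with zero mismatches:

```r
in_silico_pcr(c(fwd = top$f_sequence, rev = top$r_sequence),
              template, size = c(50, 1000))$amplicons
#>   forward_primer reverse_primer start end length total_mismatches
#> 1            fwd            rev    36 241    206                0
```

The oligo analyzer shows why low-complexity primers are filtered: a
polypurine 21-mer has an unremarkable Tm and GC but an LC of 42%,
far below the 75% acceptance threshold:

```r
oligo_report("GAGGAGGAGAGAGGAGAAGAA", "polypurine")
#>         name              sequence length    tm    gc    lc epsilon_260   mw
#> 1 polypurine GAGGAGGAGAGAGGAGAAGAA     21 61.31 52.38 41.89      242600 6691
#>   nmol_per_od ug_per_od
#> 1       4.122     27.58
```

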