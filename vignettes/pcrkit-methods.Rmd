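---
title: "Models and design rules in pcrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design rules in pcrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcrkit)
```

pcrkit is a desk-scale toolkit for oligonucleotide analysis and PCR assay
design: standard/inverse/bisulfite primer pairs, hydrolysis probes,
multiplex and tiling panels, in silico PCR, LAMP sets, allele-specific
(KASP-style) genotyping assays, Gibson assembly primers, and de novo
repeat discovery. This vignette documents the underlying models, the
defaults and why they were chosen, the numerical decisions, and the known
limitations. Everything stated here is computed by the package itself;
the test suite and `scripts/acceptance.R` exercise each claim.

## Melting temperature

Duplex stability is computed from the unified nearest-neighbor (NN)
DNA/DNA parameter set: the enthalpy and entropy of a duplex are the sum
of its dinucleotide-step contributions plus terminal initiation terms
(and an entropic symmetry correction for self-complementary oligos). The
melting temperature at 1 M Na+ is

$$T_m = \frac{\Delta H^\circ}{\Delta S^\circ + R\,\ln C_f} - 273.15,$$

with $C_f = C_T/4$ for non-self-complementary oligos (primer-excess
assumption; $C_T$ for self-complementary ones), $C_T$ = 200 nM by
default. Salt is handled in two steps: the divalent ion content is folded
into a sodium-equivalent concentration,
$[\mathrm{Na^+}]_{eq} = [\mathrm{mono}] + 120\sqrt{\max([\mathrm{Mg^{2+}}]-[\mathrm{dNTP}],\,0)}$
(mM; dNTPs chelate Mg2+ stoichiometrically, so the effective divalent
concentration is the difference), and the quadratic
monovalent correction in $\ln[\mathrm{Na^+}]$ with a GC-dependent
coefficient is applied to $1/T_m$. The default buffer (50 mM K+, 1.5 mM
Mg2+, 0.8 mM total dNTP, 200 nM oligo) matches common hot-start PCR
chemistry; under it a random 20-mer at 50% GC melts near 60 °C, which is
why the default design window is 60–62 °C.

Degenerate (IUPAC) positions contribute the arithmetic mean of the
enthalpy and entropy over all expansions of each mixed-site NN step, and
the same averaging is used for extinction coefficients and molecular
weights. This matches the behavior of batch oligo calculators and is
accurate to a fraction of a degree for one or two mixed sites; it becomes
meaningless for fully degenerate oligos, which are rejected.

Two base analogues receive deliberately simple treatment. LNA bases
(E/F/J/L for locked A/C/G/T) use the underlying base's NN parameters plus
a fixed +2 °C per locked base; a full LNA NN increment set would be more
accurate mid-sequence but the fixed increment is within ~1–2 °C for the
1–3 LNA substitutions typical of probes, and the simplification is
flagged here rather than hidden. Inosine pairs as a universal base for
matching purposes and applies a fixed −1.5 °C per residue
(`thermo_conditions(inosine_dtm=)`), since no single published NN set
covers all its pairings at these conditions.

The annealing-temperature rule combines the weaker primer with the
product: $T_a = 0.3\,T_m^{\min} + 0.7\,T_m^{prod} - 14.9$, where the
product Tm uses the long-duplex formula
$81.5 + 0.41\,GC\% - 675/L + 16.6\log_{10}[\mathrm{Na^+}]_{eq}$. It
reproduces the practical guidance that ~100 bp products amplify around
55 °C while ~1 kb products need above 60 °C, and it is monotone in
product length, never exceeding the product Tm.

## Linguistic complexity

Sequence complexity is measured by the alphabet-capacity k-mer method:

$$LC = 100 \times \frac{\sum_{k=1}^{k_{\max}} U_k}{\sum_{k=1}^{k_{\max}} \min(4^k,\ L-k+1)},$$

where $U_k$ is the number of distinct words of length $k$ observed.
100% is maximal complexity; a homopolymer scores lowest
($U_k = 1$ for every $k$). Degenerate codes are treated as opaque extra
symbols rather than expanded — expansion would inflate the observed
vocabulary — while the capacity bound stays at alphabet size 4.

The word-size cap defaults to $k_{\max} = 5$. The rationale: at primer
scale the capacity bound $\min(4^k, L-k+1)$ stops binding around
$k = 3$; for much longer words nearly every word in any sequence is
unique, so each additional word level adds $U_k \approx E_k$ to both
sums and dilutes the ratio toward 100%, erasing the contrast between
repetitive and complex sequences. Capping at one–two levels past the
crossover keeps the measure discriminative: under this cap,
polypurine-rich primers of the kind documented to misprime (e.g.
`GAGGAGGAGAGAGGAGAAGAA`) score in the 40s–60s, below the conventional
LC < 70 "low complexity" line, while typical random-sequence primers
score above 80 — consistent with the default acceptance threshold
LC ≥ 75 used in primer filtering. The cap is exposed as `k_max` for
users who want the saturating long-word variant.

Windowed LC (`windowed_complexity()`) profiles templates and reports
windows under a threshold (default 50%) as maskable intervals; it is one
of the two inputs to the "non-specific priming control" mask used during
design, the other being k-mer repeat blocks.

## Dimer screening

Primer dimers are detected by gapless local alignment: every
antiparallel offset of one oligo against the other is scanned for
maximal runs of Watson–Crick complementary bases (G·T wobbles do not
extend runs — a conservative reading of complementarity). A pair is
rejected when any run of ≥ 5 bases includes a 3'-terminal base of either
oligo, or any run reaches ≥ 7 bases anywhere. These counts implement the
"stable dimer" notion as run-length thresholds; an optional
free-energy gate (reject only if the dimer Tm reaches within 10 °C of
the annealing temperature) is available but off by default, because the
run-length rule alone is already the stricter, cheaper filter. The
"3' run" definition requires the run to include a terminal base; a
window-based alternative is available in the hairpin check
(`three_prime_window`).

Dimer and binding-site Tm values with mismatches use the published
internal single-mismatch NN parameters (including inosine pairs);
doublets with two mismatched pairs have no published values and
contribute nothing, and initiation terms are added only for paired
terminal bases (dangling-end contributions are ignored). Alignments
shorter than two NN steps, or with non-negative net enthalpy, return
`NA` ("below model range").

The 3' hairpin check enumerates stem/loop splits anchored at the 3'
terminus: an oligo is flagged when its terminal bases can fold back with
a stem of ≥ 4 bp and a loop of ≥ 3 nt. The stem threshold is a
documented knob — the check itself is required for allele-specific
primers whose extension competes with self-priming, but no universal
threshold exists.

## Primer pair design

Candidate enumeration slides all windows of the allowed lengths (default
18–22 nt, hard bounds 15–35) over both strands and keeps those within
the Tm window (60–62 °C), GC range (40–60%), LC ≥ 75, outside masked
intervals, not covering a G-quadruplex motif (≥ 4 runs of ≥ 3 G with
1–7 nt loops, either strand), and passing the self-dimer filter.
Filters run cheapest-first (vectorized window Tm/GC, then LC, then the
dimer scan); every surviving candidate's Tm is recomputed exactly, so
the fast screen never decides acceptance by itself. With
"non-specific priming control" on (the default), repeat blocks and
low-complexity windows of the template are masked before enumeration.

Pairing combines forward × reverse candidates subject to product size,
Tm balance (|ΔTm| ≤ 3 °C) and the cross-dimer filter, and ranks pairs by
a weighted score: mean LC (weight 0.30), Tm-balance penalty (0.25),
3'-end stability penalty (0.20; the GC fraction of the five 3' bases —
over-stable 3' ends misprime), GC mid-range bonus (0.15) and
product-size centrality (0.10). The weights are exposed in
`design_constraints()`; the ordering, not the absolute score, is what
matters, and ties break deterministically (leftmost forward primer, then
shortest product). Because the dimer filter does not contribute to the
score, pairs are screened in rank order and the search stops after
`max_pairs` acceptances — the returned head of the ranking is identical
to what full screening would give.

Inverse mode (circular templates) pairs a forward primer downstream of a
reverse primer so the product wraps the origin with
$L_{prod} = (L - s_F + 1) + e_R$. Bisulfite mode first converts the plus
strand (unmethylated C→T outside CpG; CpG cytosines are preserved as
they carry the methylation signal), designs on the converted sequence,
and additionally rejects candidates whose 3'-terminal base sits on a
preserved CpG base — a primer ending on a methylation-variable position
would genotype the methylation state rather than prime uniformly.

Hydrolysis probes are placed strictly between the primers. TaqMan rules:
length 15–30 nt, GC 45–65%, Tm 68–72 °C with a soft target 8–10 °C above
the mean primer Tm, no 5' guanine (G adjacent to the reporter quenches
it even after cleavage), dimer-compatible with both primers. The
reported strand is the one with more C than G in the window (standard
practice; C-rich probes quench less). MGB probes: length 13–30 nt with
sequence Tm within 1 °C of the primer Tm. The minor-groove binder's
stabilization is *not* modeled thermodynamically — no public parameter
set exists — so the output notes that the reported value is the
sequence Tm and the uplift is left to the user's chemistry.

## In silico PCR

Binding-site search is seeded on the primer's 3'-terminal 12-mer,
hashed against the template with one tolerated mismatch (the 37 query
variants of the word), then extended 5'-ward by gapless alignment. The
terminal 12 bases are the polymerase's grip on the template: a site is
kept under the default policy when it has ≤ 3 total mismatches over the
aligned part, ≤ 1 mismatch inside the 3' 12-mer, and both 3'-terminal
bases matched. 5' tails (primer prefixes overhanging the template) are
allowed and excluded from mismatch counts, but the terminal 12 bases
must lie on the template. Sites with ≥ 2 mismatches in the 3' 12-mer
are invisible to the seed — a documented sensitivity bound, matching the
biology (such primers rarely extend). The seed mismatch counts toward
the total (one unified count). Amplicons are every convergent (+,−)
site pair within size bounds (default ≤ 5,000 bp), with origin-spanning
products on circular templates; a primer yielding more than 10,000
sites triggers a repeat-explosion warning naming the primer rather than
silent truncation. Short-oligo screening (miRNA seeds, guide RNAs) is a
full-length Hamming scan capped at 3 mismatches — beyond that the hit
lists stop being informative.

## LAMP sets

A LAMP set addresses six (eight with loop primers) template regions
ordered F3 < F2 < (LF) < F1 < B1 < (LB) < B2 < B3. FIP is the exact
concatenation of the reverse complement of F1 ("F1c") with F2; BIP is
the strand mirror (B1 sequence plus reverse complement of B2). Defaults
follow the conventions popularized by the PrimerExplorer family —
core/outer primers 18–22 nt at 59–61 °C, fold-back arms F1c/B1c 18–24 nt
at 64–66 °C (they must out-melt the core primers to form the dumbbell),
loops 18–22 nt at 62–64 °C, F2→F1 spacer 20–60 nt, F3 within 20 nt of
F2, F2–B2 span 120–300 bp — and are labeled as external convention, not
derived values; all are arguments of `lamp_config()`. Repeats are masked
before candidate generation by default; all intra-set primer pairs must
pass the dimer filter; loop primers must fit wholly inside their spacers
and too-short spacers yield a flagged set rather than an error.
Bisulfite LAMP designs on the converted strand. LC thresholds are
relaxed to 70 for LAMP regions (eight simultaneous placements make 75
overly restrictive on short targets).

## Allele-specific (KASP-style) assays

A variant template `left[x/y(/z/w)]right` yields one allele-specific
primer (ASP) per allele plus one universal primer (UP). All ASPs share a
flank-derived 5' body and 3'-terminate on the discriminating base
(terminal placement) or one base past it (penultimate, implementing
"close to the 3' terminus"); a deliberate extra ARMS-style mismatch is
not added — the spec of the assay is competitive amplification, and the
penultimate option already covers weak discrimination. For indels, the
common prefix/suffix of the alleles is folded into the shared body, so
the insertion ASP ends inside the insertion and the deletion ASP spans
the junction; product lengths then differ by the indel length, which is
itself diagnostic. The UP lies entirely within the opposite flank and
therefore anneals identically to every allele. ASP length is tuned via
the shared body so the worst allele's Tm is closest to the design
window; all oligos are screened jointly for dimers, G-quadruplexes and
3' hairpins. Reporter tails (the two community-standard FAM/HEX tails
ship as `kasp_reporter_tails`) are prepended after design; they do not
touch placement or template Tm but the tailed set is re-audited and any
new dimer rejects the tails. Phased haplotypes are expressed as
multi-base alleles of a single block — one block per phase — rather
than as multiple bracket blocks; "mono-allelic" inputs (one allele)
yield a single ASP + UP presence/absence assay.

## Gibson assembly

Each fragment is amplified with terminal primers whose annealing part
starts exactly at the fragment end (the whole fragment must be in the
product); the length 15–35 nt giving a Tm inside 60–62 °C is chosen,
falling back to the closest Tm with a flag when the window is empty —
a fragment end's composition is not negotiable, so a hard error would
make many legitimate assemblies undesignable. Junction overlaps grow
from 20 bp (cap 40 bp) until the overlap Tm exceeds 50 °C; the overlap
is split evenly between the two junction primers' 5' tails, shifting
single-sided when an oligo would exceed the 60 nt synthesis cap (warn
above 50 nt). Overlap Tm uses the NN model up to 25 bp and the
long-duplex formula beyond — the NN table's validity range. With a
vector, the vector is amplified by an untailed inverse-PCR pair and the
terminal fragments carry vector-end tails. Joint dimer violations among
the full primer set are reported, not fatal: tails are dictated by
neighbor sequence, so the user must resolve them by reordering
fragments. `stitch_gibson()` reassembles the predicted amplicons by
exact overlap matching and is used as the plan's self-audit.

## Repeat discovery

The k-mer frequency transform assigns position $i$ the genome-wide
occurrence count of the canonical (strand-symmetric) k-mer starting
there (k = 12 by default; 4^12 ≈ 16.7 M words keeps random collisions
negligible below tens of Mb). Repeat blocks are maximal runs of count
≥ 2, with gaps up to k bridged, blocks shorter than 2k dropped, and the
right boundary extended by k−1 so a block covers the full extent of its
last repeated word — on planted duplications this recovers boundaries
within k bases. Blocks are then sorted by length descending and
clustered greedily: a block joins the first cluster whose founding
(longest) member has cosine similarity ≥ 0.7 between 5-mer count
vectors in either orientation, else founds a new cluster; orientation is
the argmax of forward versus reverse-complement similarity. Greedy
first-fit on the length-sorted list is deterministic and matches the
sequential procedure described for this class of tool; the similarity
metric and threshold are documented knobs, since "k-mer vector
similarity" admits many instantiations. Masking replaces block positions
with N (or lowercase) and is idempotent. The same block caller, at
design time, feeds the non-specific priming control; note that masking
during design only sees repeats *within the supplied template* — to
avoid repeats known from a larger genome, pass its blocks via `masked=`.

## Synthetic data

`generate_template()` plants duplications (optionally diverged or
inverted), microsatellites, telomere-like `(TTTAGGG)n` arrays,
low-complexity tracts and variant blocks into a uniform random
background at a requested GC, with exact truth coordinates and
byte-identical output per seed (the caller's RNG stream is preserved).
It emulates the composition of repeat-rich benchmark targets — e.g. a
~47%-repetitive template is composed by summing planted feature lengths
— but not real genomic base composition, transposon structure, or
polymorphism; passing tests on these fixtures demonstrates algorithmic
correctness (recovery, masking, closure, compatibility audits), not
performance on any particular genome.

## Problem sizes and numerical choices

The shipped tests run the full stack at desk scale: repeat recovery on
20 kb fixtures, tiling on a 6.7 kb template, multiplex on ten 400 bp
targets, LAMP on 1 kb templates, exhaustive dimer-oracle equality on
1,000 random 12-mer pairs, and seeded site-search-vs-naive-scan equality
on 200 random cases. These sizes were chosen so the whole suite
completes in a few minutes while every algorithmic path (seeding,
extension, wrap-around, masking, pool assignment) is exercised;
the algorithms themselves have no size-specific constants besides the
documented k-mer sizes. Internally all coordinates are R-native 1-based
inclusive, and every report and file format is 1-based inclusive as
well (BED exports are the usual 0-based half-open exception).
Tiling-panel geometry is the one genuinely coupled system: with
~1.2 kb amplicons, ≥ 500 bp overlaps and two pools, pool-mate
disjointness requires overlaps near the lower bound and products near
the nominal length, so the planner strides at overlap-minimum + 80 bp,
constrains products to ±50 bp of nominal, and enforces realized overlap
bounds and pool disjointness explicitly while selecting each pair,
re-searching with a widened Tm window before reporting a gap. Template
ends that no Tm-conforming primer can reach are reported as "terminal"
gaps and excluded from the coverage verdict — a tiling panel cannot
begin a primer at base 1 of an arbitrary sequence.

## Known limitations

- No partition-function secondary-structure folding: hairpin and dimer
  checks are run-length/NN-based, not mFold-style.
- Mismatch duplex Tm ignores doublets with two adjacent mismatches and
  dangling ends.
- LNA/inosine thermodynamics are fixed-increment approximations.
- MGB probe Tm uplift is not modeled.
- The seed design misses binding sites with ≥ 2 mismatches in the 3'
  12-mer unless the naive path is used.
- Repeat discovery targets desk-scale inputs (up to tens of Mb);
  there is no disk-backed index.
- GenBank/accession retrieval and any network access are out of scope;
  inputs are local FASTA/plain text only.
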