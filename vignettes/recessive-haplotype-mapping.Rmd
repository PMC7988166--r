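---
title: "Mapping recessive lethal haplotypes from survivor panels"
author: "recscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping recessive lethal haplotypes from survivor panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recscan)
```

## The problem

Intensive use of a few elite sires in closed livestock breeding
programs lets recessive deleterious alleles drift to appreciable
frequencies before any affected (homozygous) animal is ever observed —
because, for an embryonic or juvenile lethal, affected animals never
reach the genotyped adult population at all.  The observable footprint
of such an allele in a large SNP-array panel of healthy adults is a
*missing homozygosity* signal: a haplotype with population frequency
$q$ should appear homozygous in about $Nq^2$ of $N$ random-mating
individuals, and a linked recessive lethal drives that count toward
zero.

`recscan` implements the full analysis pipeline around this signal:
the genome-wide scan, the downstream epidemiological contrast on
artificial-insemination (AI) return records, Hardy–Weinberg and
segregation tests on genotype counts, the candidate-variant filter, and
splice-boundary sequence logos.  Because panels of this kind are
usually access-restricted, the package also ships a synthetic-data
generator that reproduces the statistical structure the analysis
assumes, with known ground truth, so every module is testable end to
end without any external data.

## The scan model

Phase is taken as given (phased upstream with standard software such as
BEAGLE; the package consumes diplotypes and never re-phases).  For each
window of $k$ consecutive SNPs, $k = 2, \dots, 100$, stepping one
marker at a time and never crossing a chromosome boundary, every
distinct haplotype allele string is counted: copies $c$ (so
$q = c/2N$), carriers, and homozygotes.  For each haplotype with
$q \ge$ `min_q` (default 0.01) the homozygote-deficiency p-value is the
lower tail of the binomial census model,

$$p = P(X \le \text{obs}), \qquad X \sim \mathrm{Binomial}(N,\, q^2),$$

with expected count $Nq^2$.  The test is one-sided by construction:
only a *deficit* of homozygotes is evidence for a recessive lethal.
For a haplotype at $q = 0.052$ in $N = 4843$ this gives an expectation
of about 13.1 homozygotes and $p \approx 2\times10^{-6}$ when none is
observed.

Windows with $p < 10^{-4}$ are reported, each annotated with a
Benjamini–Hochberg q-value computed over **all** performed tests
(panel-wide, across chromosomes and window sizes).  Overlapping
significant windows on a chromosome are merged transitively into risk
regions named `<prefix>_<chrom>` (suffixed `_1`, `_2`, … when one
chromosome carries several), each region reporting the statistics of
its most significant constituent window, the bp span of the union, and
the marker count inside the span.  Region length is reported as
`end − start`, matching the arithmetic of published haplotype-region
tables.

### How regions are called: window support, with the FDR as annotation

A genome-wide window scan performs millions of (window × haplotype)
tests.  Although the plug-in binomial test is conservative under the
null (the haplotype frequency is estimated from the same census, which
couples the observed homozygote count to its own expectation — we
measure per-test null rejection at roughly a quarter of nominal), a
panel of 10,000 independent markers still yields on the order of
$10^6$ eligible tests, so a handful of raw $p < 10^{-4}$ windows are
*expected* per null panel.  The two regimes differ sharply in
structure, not in raw p-value: a genuine recessive lethal spanning L
markers is rediscovered by every sub-window of every size — on the
order of $L^2/2$ overlapping significant windows (in our study-scale
simulations, 246–384 per true region) — whereas a chance
homozygote-free lineage in a null panel is supported by one to four
windows.  Region calling therefore requires a merged region to be
supported by at least `min_windows = 10` overlapping significant
windows, the formalization of calling regions from *overlapping*
haplotype windows (the stacked-window picture of such scans); the
threshold sits two orders of magnitude from both regimes, and any
value from roughly 5 to 200 behaves identically.  In 20 simulated
null panels at study scale (N = 4843, 10,000 markers) this rule calls
zero regions in every panel, while the planted lethal is recovered as
exactly one region covering the planted span.

Benjamini–Hochberg q-values over all performed tests are computed and
reported for every window and region, and an optional `max_q` gate is
available.  The q-value is deliberately *not* the default region
gate: with $m \approx 1.8$ million no-LD tests, the true cluster's
q-value scales as $e^{-N\hat q^2}\, m / \text{cluster size}$ and
crosses 0.05 whenever the sampled census frequency lands only half a
standard error below 0.05 — an unacceptable sensitivity to sampling
noise exactly at the frequency band of interest, and an artefact of
the LD-free null's enormous multiplicity rather than of the signal.

### Numerical and engineering choices

* The scan kernel (C++) refines haplotype classes incrementally: the
  class labelling for window $(s, k)$ refines $(s, k-1)$ by one marker
  column, costing $O(2N)$ per extension.  A start is abandoned once no
  class holds `min_q` of the copies, and haplotype classes that drop
  below the threshold retire permanently — window extension only ever
  splits classes.  A 10,000-marker, $N = 4843$ scan runs in about ten
  seconds on one core.
* Homozygosity means exact string identity over the window; there is
  no mismatch tolerance and no missing-data handling (inputs are
  post-imputation phased panels with complete genotypes).
* `min_q = 0.01` bounds the multiplicity; the haplotypes of interest
  sit around 0.045–0.05.
* Coordinates are half-open marker indices internally and 1-based
  inclusive bp at every interface (VCF/GTF convention).

## The synthetic cohort

`simulate_panel()` emulates the census structure the scan assumes.
Background alleles are drawn marker-independently with per-marker
alternate-allele frequencies uniform on (0.05, 0.95) — the profile of
an array panel filtered at minor-allele frequency 0.05 — deliberately
with **no background LD**: it is the simplest null, it makes the
multiplicity of the scan interpretable, and it is *harder* than real
data in the one respect that matters here (an LD-free panel performs
many more effectively independent tests than a real genome at equal
marker count, so calibration results transfer conservatively).  What
the generator consequently does not emulate: LD decay, recombination
maps, pedigree structure, genotyping error, or phasing error.  Passing
tests therefore validate the statistical machinery, not robustness to
phasing artefacts.

Each planted risk haplotype is stamped onto founder haplotypes at a
frequency chosen so that the *census* — after lethal-homozygote
removal — shows the requested `target_frequency`.  Under complete
lethality the founder frequency solves $x/(1+x) = q_t$, i.e.
$x = q_t/(1-q_t)$; the general case with penetrance $\pi$ solves
$\pi(q_t - 1)x^2 + x - q_t = 0$.  Calibrating the census rather than
the founder pool matches how risk-haplotype frequencies are actually
measured (in the survivors) and keeps the frequency-recovery invariant
exact: the estimated haplotype frequency is within three binomial
standard errors of `target_frequency`.  Individuals homozygous for the
planted string are rejected and redrawn with probability `penetrance`
(default 1), keeping the census size fixed at $N$ — the panel is a
fixed census of survivors, not a thinned cohort.  Homozygosity is
judged by string identity at the planted span, so coincidental
background copies of the planted string are handled correctly.

`simulate_matings()` generates AI service records with per-bin return
probabilities (defaults 0.10, 0.18, 0.05, 0.03, 0.02 over the bins
18–29, 30–60, 61–90, 91–140, 141+ days — around a 38% overall return
rate, typical of beef-cattle AI programs) and adds an excess return
probability (default 0.07) in one early bin (default 30–60 days, the
window in which blastocyst-stage loss returns a cow to estrus) for
carrier × carrier matings only.  `simulate_embryos()` draws embryo
genotypes 1:2:1 from het × het matings and removes risk homozygotes
before observation with a configurable probability.
`simulate_variant_table()` builds a causal variant riding the risk
haplotype plus decoys that each violate exactly one selection
criterion; `simulate_genome_annotation()` builds a toy genome whose
introns follow the GT/AG rule with configurable probability
(non-canonical boundaries are drawn explicitly non-GT/non-AG, so the
retained fraction equals the consensus strength exactly) and whose
canonical donors carry the mammalian +3…+6 consensus (A, A, G, T-rich;
G at +5 with probability 0.8).

All generators derive independent substreams from one global seed, so
a run is reproducible from its seed alone.

## Genotype-count statistics

The count-level tests mirror the published tables they reproduce:

* `allele_frequency()`: $(n_{rv} + 2n_{vv})/2N$, printed at three
  decimals with half-away-from-zero rounding (the rounding used
  wherever a printed value is matched; base R `round()` would round
  half to even).
* `hwe_expected()`: $N(1-p)^2, 2Np(1-p), Np^2$ at the unrounded
  frequency.
* `hwe_deficit_chisq()`: three-class goodness of fit with **df = 1**
  by default — the correct asymptotic df for a three-genotype test
  with the allele frequency estimated from the same counts, and the
  only choice that reproduces the published P = 0.002 (χ² = 9.56) and
  P = 0.0001 (χ² = 14.65) values.  The df is exposed as a parameter.
* `homozygote_absence_binomial()`: $(1-f^2)^N$, the companion
  one-sided test when the expected homozygote class is too small for a
  χ².
* `segregation_test()`: goodness of fit against 1:2:1 (configurable).
* `mortality_contrast()`: for one return bin, the 2×2 of
  (risk vs other mating) × (second AI in bin vs no second AI), χ²
  without continuity correction (closest to the published values;
  Yates and Fisher variants available).  Records returning in *other*
  bins are excluded from the bin's table — each bin contrasts
  "returned in this window" against "conceived" — and records with
  unknown carrier status are dropped with a count.  Returns before day
  18 are excluded: they indicate failed insemination rather than
  embryonic loss, and the first standard bin starts at 18 days.

Two published P values are documented as near-misses rather than
asserted: the 2×2 mortality tests print 0.035/0.012 where the plain
uncorrected χ² on the printed counts gives 0.033/0.011, and one
survey-cohort HWE test prints 0.024 where the printed counts give
0.0046 (df = 1) or 0.018 (df = 2).  The exact procedures behind those
cells are not recoverable from the counts; the package reproduces the
percentages, expectations and the df = 1 P values that *are* functions
of the printed counts.

## Candidate-variant prioritization

Variants are searched within the risk region ± 6 Mbp (a causal variant
can sit megabases outside the mapped haplotype while in LD with it).
The four criteria: (1) no risk-allele homozygotes; (2) allele frequency
within `freq_tol` of the haplotype frequency — default 0.05 absolute,
deliberately loose because published candidates run to about twice the
within-cohort haplotype frequency and still count as "approximately
equal"; (3) a deleterious annotation (stop/frameshift/splice-site
classes outright, missense only with a deleterious prediction;
`splice_region` is *not* auto-deleterious, so a splice-disrupting
variant that annotation tools undercall appears as a flagged
*near-miss* passing criteria 1, 2 and 4); (4) presence in all
genotyped haplotype carriers (`min_carrier_fraction = 1`, relaxable for
genotyping error).  Frequencies always use the per-variant called
sample count, so missing genotypes reduce N.  Copy-number variants
enter as pseudo-biallelic carrier-coded markers.  An independent
healthy-adult cohort with any live risk homozygote vetoes a candidate
(`survivor_homozygote_veto()`).

LD is $r^2 = D^2/(p_A(1-p_A)p_B(1-p_B))$ from phased haplotype counts,
or the squared Pearson correlation of dosages in genotype mode;
haplotype-versus-variant LD codes haplotype carriage as a pseudo-marker.
The two modes agree within 0.02 on random-mating panels of $n \ge 5000$.

## Splice-boundary logos

From a GTF and genome, each internal exon junction contributes a donor
window (last 6 exonic + first 6 intronic bases) and an acceptor window
(last 50 intronic + 2 exonic bases), read 5′→3′ along the transcript
(minus-strand windows reverse-complemented).  The window definitions
place the obligate GT at donor positions 7–8 and the AG at acceptor
positions 49–50; the donor +5 position — where a G is strongly
conserved and where a single substitution can abolish splicing — is
window column 11.  Duplicate junctions shared by transcripts are
counted once; windows running off a contig are skipped and counted.
After GT/AG filtering, position weight matrices report per-position
base frequencies and information content
$IC_j = 2 + \sum_b p_{bj}\log_2 p_{bj}$ bits, with N bases excluded
from the position's denominator and no small-sample correction by
default (available as an option).  Published genome-wide boundary
counts depend on the annotation release and are not desk-reproducible
targets; the module's correctness is established on synthetic
annotations with known truth.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_samples = 4843, n_chromosomes = 2,
                  markers_per_chromosome = 5000,
                  risk_haplotypes = list(planted_haplotype(
                    "1", c(2000, 2030), target_frequency = 0.05)),
                  seed = 1)
sim <- simulate_panel(cfg)
win <- scan_haplotypes(sim$panel, alpha = 1e-4)
merge_regions(win, prefix = "SIM")
```

## Problem sizes used in the shipped checks

The shipped tests and the acceptance script run the scan at
$N = 4843$ with 10,000 markers (one lethal panel plus 20 null panels),
the replicate-recovery property at 250 markers × 50 seeds (recovery
power depends on $N$ and $q$, not on the marker count), the mating
power study at 50,000 records × 100 seeds, and the type-I study at
1,500 records × 1000 seeds.  These sizes were chosen so the full
pipeline demonstrates its properties at the study's census scale while
a complete run stays in the minutes range on a single core.

## Known limitations

* No background LD in the generator means the FDR behaviour measured
  here brackets, but does not equal, that of a real LD-structured
  panel.
* The scan trusts phase and completeness; phasing error at low
  haplotype frequencies would bias carrier counts in real data.
* Expected homozygote counts use the random-mating $Nq^2$; no
  pedigree-based carrier-mating correction is applied.
* X-chromosome dosage, imputation, CNV segmentation and functional
  annotation are out of scope; annotations are consumed as labels.
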