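---
title: "Methods and design of numtkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of numtkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numtkit)
```

# The problem

Nuclear mitochondrial DNA segments (NUMTs) are fragments of the
mitochondrial genome that have integrated into nuclear chromosomes.  They
segregate in human populations like any other insertion polymorphism: some
are ancient and near-fixed, most are rare, and their breakpoints can be read
out of short-read sequencing data.  Because the mitochondrial genome is
circular and tiny (16,569 bp for the standard human reference), a NUMT is
fully described by a nuclear insertion point and an *ordered* pair of
mitochondrial breakpoints that may wrap through the replication origin.

numtkit implements a complete analysis chain around these objects:

1. **Detection** of per-individual insertions from abstracted read evidence
   (discordant mate pairs and split reads).
2. **Cohort merging** of per-individual calls into population-level loci
   with carrier counts and frequency classes.
3. **Introgression analysis**: reconstruction of archaic (Neanderthal /
   Denisovan) introgressed segments from Sprime-style output, and a
   permutation test for whether NUMTs co-occur with such segments more often
   than chance.
4. **Selection scan** over NUMT allele frequencies with the population
   branch statistic (PBS), z-score outliers, and a block jackknife.
5. **Enrichment**: permutation tests for insertion-site preference against
   nuclear annotation tracks, and a sliding-window hotspot scan of NUMT
   origins on the circular mitochondrial genome.
6. **Sequence tools**: per-individual consensus construction from pileups,
   recurrence testing via pairwise identity with hypervariable-region
   masking, and reading-frame classification under the vertebrate
   mitochondrial genetic code.
7. **Synthetic data**: seeded generators for every input format, with
   planted ground truth.

Read alignment itself (and BLAT-style realignment) is out of scope: the
package consumes evidence records that an aligner pipeline produces.

# Coordinate conventions

Internally all nuclear intervals are 0-based half-open, which makes interval
arithmetic unambiguous; every table written for human consumption renders
1-based inclusive positions, and BED I/O is 0-based half-open as the format
requires.  Mitochondrial breakpoints are 1-based positions on the circle.
The length of a fragment with breakpoints $(s, e)$ on a circle of length $L$
is

$$\mathrm{len}(s, e) = (e - s) \bmod L,$$

which handles origin-spanning fragments (e.g. breakpoints 16,088 and 61 give
542 bp, not a negative number).  This rule is consistent with every
non-wrapping fragment's printed length and is rotation-invariant, which the
test suite asserts as a property.

# Detection model and thresholds

Evidence records carry a mapping quality; records with MAPQ 0 are discarded
(multi-mappers carry no positional information).  Discordant pairs are
clustered per chromosome and orientation by **single-linkage with a 500-bp
gap threshold**: the underlying rule is only "within 500 bp", and
single-linkage on sorted anchors is the simplest deterministic reading.  A
cluster needs at least two pairs.

A call requires three breakpoints: one nuclear and two mitochondrial.  In
`modern` mode each must be split-read supported (so at least three split
reads, with two distinct mitochondrial positions).  In `archaic` mode —
meant for degraded, short-insert ancient libraries where split reads are
scarce — a single supporting split read suffices, and breakpoints without
split support fall back to discordant-pair evidence: the modal anchor
position on the nuclear side, the extreme mate positions on the
mitochondrial side.  Breakpoints are modal positions with ties broken
toward the smaller coordinate (determinism).  The two mitochondrial
positions are oriented into a (start, end) pair by choosing the circular
reading that contains more of the discordant mates, breaking ties toward
the shorter fragment.

Calls whose local coverage strictly exceeds **200×** are removed (collapsed
repeats and reference-embedded NUMT copies), as are calls overlapping an
optional mask of reference-assembly NUMTs.

# Cohort merging

Nuclear breakpoints across individuals are chained per chromosome by
single-linkage with a **1000-bp** gap.  The merged locus interval runs from
the smallest to the second-smallest distinct member start; a degenerate
single-start cluster becomes a point interval (the convention the merged
tables print).  Mitochondrial breakpoints are selected independently as the
modal observed start and modal observed end — a single-pass reading of
"most frequent position"; we do not iterate re-assignment rounds, and the
merge is idempotent under re-clustering because consecutive merged loci are
by construction more than 1000 bp apart.

Carrier counting is per individual per locus (an individual contributing
two member calls counts once).  Frequencies are reported with **explicit
denominators**: per-population counts against the panel sizes, and a pooled
frequency against the summed panel.  Frequency classes partition carrier
frequency $F$ as prevalent ($F > 10\%$), common ($1\% \le F \le 10\%$),
rare ($0.1\% \le F < 1\%$) and ultrarare ($F < 0.1\%$); the boundary
placement is asserted by tests.  Display statistics (mean/median/SD of
fragment lengths) round half-up, the convention needed so that e.g. a mean
of 162.5 prints as 163.

# The overlap permutation test

For individual $i$ with $n_i$ NUMTs, the empirical overlap rate is

$$R_i = \frac{\#\{\text{NUMTs of } i \text{ intersecting an introgressed
segment of } i\}}{n_i},$$

with intersection meaning a nonempty half-open overlap (≥ 1 bp).  The test
statistic is the mean $\bar R$ over the analysis set.  Each permutation
replicate reassigns to every analysis individual the **complete segment
set of a uniformly drawn different individual** from the cohort pool,
keeping segments at their genomic coordinates, and recomputes the mean.
Reassigning whole sets (rather than resampling individual segments)
preserves each individual's within-genome segment structure — number,
lengths and spacing — which is the exchangeable unit under the null that
segments and NUMTs are unlinked.  The one-sided enrichment p-value is the
fraction of replicate means $\ge \bar R$; when no replicate reaches it the
result is reported as the bound $p < 1/n_{\mathrm{perm}}$ (at the default
5000 replicates, $p < 0.0002$).

Two analysis-set definitions are supported: individuals whose own NUMTs
overlap their own segments at least once (the default, matching how such
cohorts are typically conditioned), and all NUMT carriers.  The
conditioned set is *not* suitable for type-I-error statements — selecting
individuals by their observed overlap biases $\bar R$ upward — so the
calibration property in the test suite uses the all-carriers set, for which
the permutation is exchangeable.  Implementation note: because a replicate
only needs the overlap rate of carrier $i$ against donor $j$'s segment set,
the package precomputes the full rate matrix once and permutation becomes
index sampling; 5000 replicates cost milliseconds.

Haplotype colocalization of a NUMT and an overlapping segment is classified
from genotypes and (where available) phase: `same-haplotype`
(het/het phased together), `different-haplotype`, `consistent-coinheritance`
(hom with het — every haplotype carrying the rarer state carries the
other), `shared` (hom/hom) and `uninformative`.

## Sprime-style segment reconstruction

Sprime-like callers emit candidate segments with the archaic-specific
allele at each member site.  Per haplotype, maximal runs of consecutive
archaic-allele-carrying sites within one segment id become segments spanning
the first to last site.  The minimum run length is 2 (configurable): a
single site has no extent and single-marker runs are dominated by genotype
error.

# The PBS selection scan

For a pair of populations with allele frequencies $p_1, p_2$ and sample
sizes $n_1, n_2$ (haplotypes), the package uses **Hudson's estimator**

$$\hat F_{ST} = \frac{(p_1 - p_2)^2 - \frac{p_1(1-p_1)}{n_1 - 1} -
\frac{p_2(1-p_2)}{n_2 - 1}}{p_1(1 - p_2) + p_2(1 - p_1)},$$

chosen because it is the standard two-population estimator for PBS scans
and nearly unbiased under unequal sample sizes.  Estimates are clamped to
$[0, 1 - 10^{-9}]$ so the branch transform $T = -\log(1 - F_{ST})$ stays
finite.  For a triplet (A = focal, B = sister, C = outgroup),

$$\mathrm{PBS}_A = \frac{T_{AB} + T_{AC} - T_{BC}}{2},$$

and the identity $\mathrm{PBS}_A + \mathrm{PBS}_B = T_{AB}$ is asserted
numerically to $10^{-12}$.  The focal population is the one with the
highest allele frequency at the locus (ties break toward the larger sample,
then alphabetically — documented, not asserted as the only defensible
choice); sisters come from the focal continent, except that an Oceanian
focal population draws its sisters from East Asia (Oceanian panels are too
small to supply an ingroup); outgroups come from a third continent.  All
(sister, outgroup) pairs are enumerated and the maximum PBS kept.  NUMT
"allele frequency" defaults to the carrier frequency as a haploid proxy,
since short-read evidence does not reliably genotype insertions;
genotype-based frequencies can be supplied instead.

Outliers are flagged at $|Z| > 2$ over the per-locus maximum PBS values.
The **block jackknife** removes, in turn, each genomic window (500 kb or
1 Mb) containing at least one locus and recomputes z-scores; the report
gives, per locus, the fraction of iterations in which its outlier status is
unchanged.  Windows whose removal leaves fewer than three loci are skipped
(no z-score is defined there).

Nearest-gene assignment extends the locus by ±5 kb and takes the gene at
minimal distance (0 when overlapping; ties alphabetical).  The expression
association test takes loci with ≥ 10 carriers, selects genes within
±200 kb, and compares carriers against non-carriers with a two-sided
Wilcoxon rank-sum test at $\alpha = 0.05$.  An XP-EHH column is reserved in
the report schema for externally computed haplotype statistics; the package
does not compute them.

# Enrichment and hotspots

Insertion-site enrichment extends each NUMT by ±100 bp and counts NUMTs
(once each) touching the annotation track.  The null draws the same number
of insertion points uniformly — chromosome proportional to length, position
uniform — and the two-tailed empirical p-value uses the add-one convention

$$p = \min\!\left(1,\; \frac{2\min(g + 1,\; l + 1)}{n_{\mathrm{perm}} + 1}
\right),$$

where $g$ and $l$ count replicates at or above / at or below the observed
count.  The raw exceedance fractions are reported alongside so the
minimum attainable value at a given replicate count is transparent.

The mitochondrial origin scan computes, in 50-bp windows sliding so that
adjacent windows share 10 bp (step 40 bp — the only reading under which
"50-bp windows with a 10-bp overlap" tiles the circle; the step is
configurable), the mean per-base count of NUMT fragments covering each
position, wrapping the origin.  Coverage is unweighted by default (each
merged locus counts once); a frequency-weighted mode is available since
either convention is defensible and they answer slightly different
questions.  The null re-places the same number of fragments with the same
lengths at uniform circular starts — total covered base pairs are conserved
in every replicate by construction — and windows significant at $p < 0.05$
in the enrichment direction are merged (overlapping or abutting, circularly)
into hotspot intervals.

A practical note on calibration: with few fragments the window statistic is
heavily tied (it takes values on a grid), and the add-one two-tailed p is
then conservative — fewer than 5% of null windows reach $p < 0.05$.  At a
cohort-scale fragment count (hundreds of fragments) the statistic is
near-continuous and the test suite verifies the null rejection rate is
within 0.05 ± 0.02.

# Consensus, identity, and reading frames

Per-individual consensus calling applies, per fragment position: discard
bases with phred quality < 10; call `N` if fewer than 3 reads remain; if
more than one allele is observed and the major allele's fraction is below
0.75, call `N`; otherwise call the major allele.  A position with a single
observed allele and depth ≥ 3 is called directly — we read the 0.75 rule as
applying "at heterozygous sites" only.  Note that with mixed qualities and
mixed alleles, raising the quality threshold can legitimately flip an
ambiguous position to a confident call (discarding low-quality minor-allele
reads removes the ambiguity), so threshold monotonicity holds — and is
tested — for single-allele positions.  The representative sequence across
individuals takes the per-position majority non-`N` allele, ties broken
alphabetically.

Pairwise identity is matches over compared positions, excluding positions
with `N` in either sequence and positions in an optional mask.  The default
mask covers the hypervariable control-region segments HVS-I (16,024–16,365)
and HVS-II (57–372) in rCRS coordinates — the fastest-mutating part of the
molecule, which can make independent insertions look divergent and a single
ancient insertion look recurrent; both masked and unmasked identities are
reported.

Reading-frame classification aligns a fragment to each overlapping
protein-coding gene **by coordinate** (the fragment's mitochondrial
coordinates define the alignment; there are no indels unless the sequence
contains `-` characters).  The overlap is trimmed to complete codons of the
gene's frame (incomplete terminal codons are dropped, not padded), handling
the one light-strand gene (ND6) by reverse complement.  The frame is intact
if no partial-codon gap occurs (a fully deleted codon is an in-frame
deletion and is skipped; any other gap is a frameshift) and translation
under the **vertebrate mitochondrial code** (translation table 2 — with its
nonstandard assignments: TGA = Trp, ATA = Met, AGA/AGG = stop) produces no
premature stop.  For intact frames, each codon differing from the reference
contributes its nucleotide differences to the synonymous count when the
amino acid is unchanged and to the nonsynonymous count otherwise.  This
simple per-codon rule — rather than Nei–Gojobori pathway averaging — is a
deliberate simplification: multi-hit codons are rare at the divergences
involved, and the rule keeps `syn + nonsyn` exactly equal to the differing
nucleotide count, which the suite asserts.

# The synthetic cohort generator

The generator emulates the statistical structure the pipeline assumes, with
one master seed driving fixed per-stage substreams (cohort, evidence,
pileups, Sprime output) so stages can be regenerated in isolation.

* **Cohort**: a toy genome of five 1-Mb chromosomes and a 16,569-bp
  circular mtDNA; three populations of 20 on two continents.  These sizes
  keep every property test below a minute while leaving room for tens of
  loci and hundreds of tracts.
* **NUMT loci**: default 10 loci, lengths uniform on 60–600 bp (short
  insertions dominate real callsets), per-population carrier frequencies
  uniform on 0.05–0.5 unless a frequency matrix is supplied.
* **Introgression**: the co-occurrence probability θ is the probability
  that a carried NUMT lies inside a tract on the carrying haplotype (θ = 1
  plants every NUMT inside a tract; θ = 0 places tracts independently).
  Tract lengths are uniform on 20–60 kb — introgressed haplotypes are
  orders of magnitude longer than NUMTs, which is exactly why embedding is
  informative.  Background tracts arrive per individual as Poisson(2).
  Overlapping tracts on one haplotype are unioned, as a segment caller
  would report them.
* **Evidence**: each planted NUMT emits ≥ 2 discordant pairs with anchors
  within 500 bp of the breakpoint and 3 split reads at each of the three
  breakpoints; qualities are uniform on 30–60, 5% of records get MAPQ 0,
  and background noise pairs arrive as Poisson(1) per individual.  The
  archaic profile drops each split read independently with probability 1/2
  ("halved split support"), which makes modern-mode thresholds miss loci
  that archaic mode recovers.
* **Pileups**: per-position depth Poisson(30), base errors at 1%, phred
  qualities normal(35, 4) clipped to [2, 41]; each locus carries 2 planted
  substitutions relative to the reference.
* **Sprime output**: each true segment emits archaic-specific sites at its
  boundaries plus interior sites every ~10 kb on the carrying haplotype, so
  reconstruction round-trips to the true spans.
* **PBS model**: three populations on two continents; null loci share an
  ancestral frequency with binomial sampling noise; one planted locus has
  frequency 0.6 in the focal population versus 0.05 elsewhere.

What the generator does **not** emulate: linkage disequilibrium and
realistic demography (tracts and NUMTs are placed independently given θ),
alignment artifacts, ancient-DNA damage, heteroplasmy, and reference-NUMT
confusion.  Passing recovery tests therefore demonstrates correctness of
the algorithms under their stated assumptions, not performance on real
archives.

# Problem sizes used by the test suite

The suite runs detection recovery over 20 seeds (recall ≥ 95% required),
permutation-test calibration over 200 seeded null cohorts of 25 individuals
at 199 replicates each, top-z recovery of the planted PBS locus over 20
seeds (≥ 90% required), and hotspot null calibration over 50 seeds of
483-fragment datasets at 399 replicates.  These sizes were chosen so each
property has enough replication to be statistically meaningful while the
whole suite stays in the minutes range.

# Known limitations

* The archaic detection mode represents the relaxed split-read threshold
  only; multi-reference mitochondrial remapping and manual breakpoint
  rescue are not modeled.
* The permutation test treats individuals as exchangeable; population
  structure in segment abundance would require a stratified pool
  (`pool_ids` allows restricting the donor pool).
* PBS z-scores treat the per-locus maxima as a single distribution; no
  attempt is made to model the maximum-over-triplets selection effect.
* The ORF classifier's coordinate alignment cannot detect NUMTs that
  realigned with indels unless gap characters are supplied.
* Pooled cohort frequencies depend on the chosen denominator; the package
  always reports the denominator it used rather than a single headline
  percentage.
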