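---
title: "Reconstructing clonal architecture from multi-region tumor sequencing"
author: "clonarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing clonal architecture from multi-region tumor sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonarch)
```

## Scope and model

`clonarch` analyses tumors sequenced in several spatially distinct sectors.
Its unit of evidence is the *presence* of a somatic mutation in a sector,
established by read-count filters rather than raw caller output, and the
allele-specific integer copy-number segmentation of each sector with its
purity. Everything upstream — alignment, variant calling, array
segmentation — is out of scope: the package consumes count tables and
SEG-like files.

The underlying model of tumor growth is a clone tree: a founding clone
accumulates the truncal mutations, descendant clones diversify regionally,
and each sector is dominated by one clade. Under that model the detection
pattern of a mutation across sectors identifies its age class: present
everywhere (trunk, predating the last complete sweep), in several but not
all sectors (branch), or in exactly one (private). The package deliberately
does not deconvolve mixtures of clones within a sector; sectors are treated
as units, which is the resolution the data support and the convention in
multi-region studies.

## Variant filtering and validation

Exome SNVs pass when the normal sample shows at most 5 variant reads at a
frequency of at most 0.05, the tumor shows at least 6 variant reads, and
the tumor VAF is either at least 0.2 or at least 10 times the normal VAF
(the rescue rule for low-frequency calls). Exome indels need more than 4
supporting reads and VAF at least 0.1. Deep-sequencing validation requires
exome membership, at least 10 alternate reads (15 when the VAF is below
0.05), tumor VAF at least 5 times normal and at least 0.01; deep-sequenced
indels additionally need at most 90% of alternate reads on one strand and
VAF at least 0.03.

Three boundary conventions are configurable but have defaults:

* the 0.2 tumor-VAF boundary in the exome rescue rule is inclusive
  (`lowVafInclusive = TRUE`); the rule texts say "below 0.2" gets extra
  scrutiny, so exactly 0.2 passes;
* a normal VAF of zero passes every tumor/normal ratio rule — the limit of
  the ratio test;
* VAF denominators are `alt + ref` of the modeled alleles, not total depth;
  other-allele reads are not part of the data model.

Germline subtraction is represented as an optional blacklist of mutation
keys (`filterVariants(..., germlineBlacklist = )`); germline calling itself
is upstream of this package.

## Presence, pITH and trees

A mutation is present in a sector when it passes deep-seq validation there,
falling back to the exome decision only where no deep-seq assay covers that
mutation/sector — only validated variants feed the phylogenies. pITH is the
percentage of branch plus private mutations and complements the trunk
percentage exactly.

Sector distances are Hamming distances on the binary profiles; an
all-absent "normal" taxon is appended so that the edge between normal and
the first internal node renders the trunk (its length equals the truncal
burden for additive data). Trees are built by the package's own
neighbor-joining implementation (Q-criterion agglomeration, three-point
resolution of the final triple, negative branch lengths clamped to zero);
the test suite verifies it against an independent reference implementation
on random additive matrices, where both recover the generating topology.

Because the trunk fraction shrinks as more sectors are examined,
cross-cohort comparisons subsample: `subsampleTrunkRatio()` draws *k*
sectors (default workflow: *k* = 3, 20 iterations) and recomputes the trunk
over detected mutations; `burdenGain()` reports the union burden of the *k*
drawn sectors over their mean single-sector burden, minus one. The
denominator choice is genuinely open — the mean of the same *k* drawn
sectors is the default because it uses exactly the information a
*k*-sector study would have; the first-drawn sector and the patient-wide
mean are available as options. Both statistics are validated against
exhaustive enumeration over all sector subsets on small matrices.

## Copy-number instability

The reference ploidy of a sector is the weighted median of per-segment
total copy number — SNP-count weights when every segment has them,
otherwise length weights — with ties resolved downward. GII is the genome
length fraction whose total copy number deviates from ploidy by at least 1;
adGII by at least 2. Two conventions to note:

* deviations are on **total** copy number, so copy-neutral LOH does not
  count toward GII (LOH is reported separately as `nMinor = 0` with at
  least one copy remaining);
* genome fractions use the covered length of autosomes only by default
  (`includeX` switches), avoiding sex-chromosome ploidy ambiguity.

Gene/cytoband copy numbers come from overlapping features with segments: a
feature overlapped by a single segment inherits its copy number; among
multiple overlapping segments only those covering at least 25% of the
feature are eligible and the largest overlap wins; otherwise the feature is
unassigned. SCNA-level heterogeneity compares per-sector deviation
*directions* (sign of CN − ploidy): same non-zero sign in all sectors is
truncal, any other non-zero pattern (partial or conflicting) is late.
Direction rather than magnitude is compared because gains and losses, not
exact copy counts, are the reproducible signal across sectors. Tumors
contribute only with at least three profiled sectors.

## Whole-genome doubling

The observed statistic `T_obs` is the genome length fraction with major
allele copy number ≥ 2 — near 1 after a doubling, near the gained fraction
otherwise. The null asks how much of that fraction piecemeal single-copy
events could generate: on the sample's own segment grid, initialized to
1+1, each segment independently gains a copy with probability equal to the
observed length fraction of the genome above the median integer ploidy
(losses, at the below-ploidy fraction, cannot raise the major allele from
the unit state). The p-value is `(1 + #{T_sim ≥ T_obs})/(1 + n_sim)` with
10,000 simulations by default. Event rates are measured relative to the
median integer ploidy — the same reference used for every other relative
call; measuring them against a fixed diploid expectation would make the
test degenerate for tetraploid genomes (everything would count as gained
and the null would reproduce the observation). Decision thresholds depend
on ploidy: below or at 3, doubled requires p < 0.001; at 4, p < 0.05 (a
tetraploid genome leaves little room for the statistic to exceed its
observed value, so the strict threshold would under-call); above 4, doubled
unconditionally. Calibration is tested empirically: over 200 simulated
non-doubled genomes the false-positive rate is ≤ 0.5%, and over 200 doubled
genomes detection is ≥ 99%.

## Cancer cell fraction and timing

For purity ρ, local total copy number `CN_t` and mutation VAF *f*, the
mutant allele copy number is `n_mut = f/ρ · (ρ·CN_t + 2(1−ρ))`. The integer
multiplicity is `round(n_mut)` clamped to `[1, CN_major]` — a mutation
cannot occupy more copies than the larger haplotype — and
`CCF = n_mut / m`, not forcibly capped at 1 (values above 1 flag purity or
copy-number misfit rather than being hidden). The 95% interval is
Clopper–Pearson on the VAF, propagated through the same linear map at the
fixed multiplicity: exact, deterministic and conservative, which is what a
clonality call should be. A mutation is clonal when the interval spans 1.

Timing relative to gains/doubling follows hard eligibility rules: indels,
1+1 regions and single-copy regions are never timed (`not_evaluable`);
among the rest, *early* requires clonal status and rounded multiplicity
≥ 2 — a mutation present on two copies must have preceded the event that
created the second copy. Everything else is *late*.

## Driver dominance

For each catalog driver gene *i* with carriers `j = 1..N_i`,
`D_i = (Σ_j 1/d_j)/N_i` where `d_j` is the number of distinct catalog
driver genes non-silently mutated in patient *j*. Gene-level counting of
`d_j` is the default — two hits in the same gene are one driver event for
self-sufficiency purposes, and event-level counting would let hypermutated
samples dominate; `countBy = "event"` provides the alternative reading.
Genes with fewer than 5 carriers are excluded (too few observations to
estimate a mean reciprocal), and ranking breaks ties by carrier count then
gene name. The shipped driver lists under `inst/extdata/` are editable
example catalogs, not a frozen authority.

## The simulator: what it emulates and what it does not

`simConfig()` defaults encode the cohort structure the package targets: 16
patients, 3–11 sectors, ~95 confirmed mutations per tumor with an indel
fraction of 71/1521, exome depth 114X and deep-seq depth 3860X, per-tumor
trunk fraction drawn from Beta(4.9, 8.1) (mean 0.377, giving a cohort pITH
median near 62% with a realistic 30–80% spread), whole-genome doubling in
12/16 tumors applied truncally (80% of truncal mutations predating it), a
per-sector altered genome fraction of 0.48 with a 15% high-amplitude
share, 60% of the altered genome shared across sectors, copy-number
profiles for 61/79 of sectors, and purity uniform on (0.4, 0.9) — a range
an allele-specific caller would accept, with purity 1 excluded as
unidentifiable. These defaults are the study conditions; tests and the
acceptance script vary only the cohort size and per-run seeds.

Mechanically, each tumor gets a random binary clone topology over its
sectors; trunk mutations sit on the root edge, branch mutations on random
internal edges, private mutations on leaves. Copy-number profiles live on
a 40-segment grid over the 22 autosomes (longest chromosomes split at a
random interior point); WGD doubles both alleles, then gains add to the
major allele and losses strip the minor first. Mutations are placed on
segments retaining at least one copy in every sector, so the emitted truth
is observable by construction. Read counts are binomial around the
expected VAF `ρ·m·CCF/(ρ·CN_t + 2(1−ρ))` at Poisson depth, with clonal
CCF = 1 within carrier sectors and an optional symmetric error floor
(default 0) for filter stress tests.

What the simulator does **not** model — and therefore what green tests do
not certify about real data: subclonal mixtures within a sector, mutation
signature context, copy-number subclonality below the sector level,
germline contamination or artifacts (so validation rates on simulated
cohorts are ~1 rather than the 0.85–0.95 seen when real exome false
positives are in the denominator), and real purity/ploidy estimation
error. The simulator validates the estimators' logic; it cannot validate
upstream calling quality.

## Numerical choices and degenerate inputs

* Weighted-median ploidy ties resolve to the lower integer.
* NJ clamps negative branch lengths to zero; an all-zero distance matrix
  yields zero-length edges; two taxa return a degenerate tree with a
  warning.
* The WGD p-value uses the add-one (permutation-style) estimator, so it is
  never zero and valid at any `n_sim`.
* Zero tumor depth is an error in SNV filters and CCF (VAF undefined); a
  deep-seq indel with zero alternate reads fails the strand rule rather
  than erroring, because an undefined strand fraction is a fail condition,
  not a malformed input.
* Per-patient RNG streams are derived from the master seed and a hash of
  the patient identifier, so cohort results are independent of patient
  order.
* Problem sizes in the test suite (matrix counts, replicate counts, null
  simulation sizes) are chosen so the full suite and the acceptance script
  each run in a few minutes on one CPU while keeping Monte-Carlo bands
  (3 SEs, binomial tolerances) meaningful.

## Known limitations

Sectors are the atomic unit: regionally mixed clones bias pITH downward
and can make late events look truncal. The WGD null treats segments as
exchangeable and events as independent, ignoring chromosome-arm
correlation; it is one concretization of a simulation null with observed
event rates, and its parameters (`pGain`, `pLoss`, `nSim`) are exposed.
CCF intervals reflect binomial counting error only, not purity or
copy-number uncertainty. The dominance score is descriptive — no
significance test is attached, and it inherits whatever ascertainment bias
the input cohort carries.
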