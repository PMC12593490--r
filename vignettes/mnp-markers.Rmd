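---
title: "MNP markers for fungal variety identification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MNP markers for fungal variety identification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnpkit)
```

## The problem

Industrially cultivated mushrooms propagate almost exclusively by cloning, so
commercially traded strains of a species such as *Hypsizygus marmoreus* are
often the same variety under different names. Single markers (ISSR bands,
antagonism plates) discriminate poorly and reproduce badly. The approach
implemented here genotypes strains at a panel of **multiple nucleotide
polymorphism (MNP) markers**: short genomic windows (100 bp) containing
several clustered SNPs whose joint allele combination — the *haplotype word*
read from a single sequencing fragment — behaves as one highly multi-allelic
marker. A library of such markers supports a simple, auditable similarity
statistic and can be extended strain-by-strain without re-running the whole
panel.

`mnpkit` implements the full desk side of that workflow: callset quality
control, marker discovery, read-count genotyping, the genetic-similarity
matrix with clustering, a sequencing-depth titration, an ISSR comparator, and
a population simulator that makes every stage testable without sequencing
data.

## Callset quality control

Input is a multi-sample VCF with per-sample `GT`/`DP` and the usual GATK site
annotations. Filtering happens in a cascade whose every comparison is strict
exactly as conventionally printed:

* **Hard filters** (`apply_hard_filters()`): a SNP record is removed iff
  QD < 2.0, FS > 60.0, MQ < 40.0, SOR > 3.0 or MQRankSum < −12.5; an InDel
  iff QD < 2.0, FS > 200.0 or SOR > 10.0. Boundary values are retained, and
  an absent annotation never triggers removal.
* **Population filters** (`filter_maf_missing()`): minor allele frequency —
  the second most frequent allele among non-missing diploid calls — below
  0.05, or a missing-call rate above 0.20, removes the site. A site with no
  usable call falls under the missing-rate rule.
* **Site depth** (`filter_site_depth()`): the summed per-sample `DP` must lie
  strictly between 10 and 2000. *Summed* depth is a design decision: the
  bound pair is only plausible as a total across tens of samples, and no
  per-sample reading yields a sensible 2000 cutoff.
* **Polymorphic screen** (`polymorphic_screen()`): a marker-grade site needs
  depth > 10 in *every* sample, no missing genotype, and a modal genotype
  carried by at most 95% of samples. The 95% rule is read as "most frequent
  genotype fraction ≤ 0.95", the most literal interpretation that still
  screens for polymorphism.

`variant_density()` reports chromosome-level variant rates as
`floor(length / n_variants)` bases per variant; flooring (not rounding) is
what reproduces all twelve rows of the packaged reference table
(`inst/extdata/hm_chromosome_variants.tsv`), including the two rows where the
two conventions disagree.

## Marker discovery

`scan_windows()` anchors one 100-bp window at every SNP position and keeps
windows holding 2–10 SNPs. Anchoring at SNPs rather than sliding by a step is
a deliberate choice: it is deterministic, needs no step parameter, and the
candidate set is provably complete — any base-anchored window's SNP set is
contained in the set of the window anchored at its leftmost SNP, so the
SNP-anchored candidates are exactly the subset-maximal windows. The test
suite enforces this equivalence against an exhaustive base-anchored oracle.

Each candidate is scored by the polymorphism information content of its
genotype-word distribution across samples. Since phase is unknowable for a
dikaryotic heterozygote called from short reads, words are built from
unphased diploid calls: `R` for homozygous reference, the allele index for an
alternate homozygote, and the sorted index pair for a heterozygote. The
default PIC is Nei's gene diversity

$$\mathrm{PIC} = 1 - \sum_i p_i^2,$$

with Botstein's marker-informativeness variant
($1-\sum p_i^2-\sum_{i<j}2p_i^2p_j^2$) available as an option; the choice is
exposed because the field uses both under the same name.

`select_markers()` keeps candidates with PIC ≥ 0.5 (inclusive) and enforces
marker spacing greedily left-to-right: a candidate is accepted iff its start
exceeds the last accepted start by strictly more than 50 kb. Spacing is
measured start-to-start; "adjacent window spacing" could also be read
end-to-start, and start-to-start was chosen for simplicity and documented
here. A `rank_by_pic` alternative exists but is off by default — the greedy
positional rule is order-deterministic and matches the oracle.

## Genotyping from read counts

A strain is genotyped per marker from the counts of window haplotypes
observed on fragments spanning all of the marker's SNPs
(`call_genotype()`):

* fewer than 10 total reads → MISSING. The floor is a package decision
  aligned with the >10× per-sample depth language of the screen; no explicit
  value is conventional.
* a haplotype is retained iff its read fraction is **≥ 0.1**. The threshold
  is applied per-haplotype (not as a minor/major ratio) and inclusively —
  both readings are defensible, so both the interpretation and the value are
  configurable, and the boundary (exactly 0.10) is unit-tested.
* at most two haplotypes are kept — a dikaryon carries two nuclei. If more
  than two pass, the two largest counts win (ties broken lexicographically)
  and a condition of class `mnpkit_excess_haplotypes` is signalled, since
  that pattern indicates contamination or error.

Profiles assemble into an `mnp_db` (`build_database()`, `db_add_strain()`),
which is deliberately incremental: identifying a new variety means genotyping
it once and appending, never re-building the library. The on-disk form
(`save_database()`) is a schema-tagged, versioned JSON container rather than
a language-native binary dump; round-trip identity is enforced by tests, and
a version bump fails loudly instead of mis-reading.

## Genetic similarity

For two profiles, `compute_gs()` counts markers with *identical* haplotype
sets — a heterozygote matches only the same unordered pair; partial overlap
is a non-match — and reports

$$\mathrm{GS}(\%) = \frac{n}{N} \times 100,$$

rounded half-away-from-zero to two decimals (base R's round-half-even fails
on values such as 255/369). `mode = "total"` takes N as the library size and
counts MISSING-in-either as a non-match, matching the statistic's published
definition; `mode = "shared"` restricts N to markers called in both, which is
more forgiving of dropout in real data. Both are shipped because the
reference treatment of MISSING is not stated anywhere.

`classify_pair()` applies the identity rule: GS ≥ 99% (inclusive) means
"same or highly similar variety". `cluster_gs()` converts similarity to
distance `1 − GS/100` and clusters agglomeratively; average linkage (UPGMA)
is the default, with the linkage method configurable because published
heatmaps rarely state it — tree topology is therefore qualitative, not
bit-reproducible.

## Depth titration

`titration_curve()` answers "how deep is deep enough": it binomially thins a
deep count table to a grid of target depths (each read kept with probability
`target/full`), re-genotypes, and counts markers whose call differs from the
full-depth profile. Newly-MISSING markers are tallied separately from
discordant ones — a lost call is not a wrong call. Binomial thinning is the
standard reproducible analogue of re-sequencing at lower depth; with
error-free reads the expected discordance is monotone non-increasing in
depth and reaches zero near 40×, which the acceptance suite checks on
simulated data (1,300 markers, 20 replicates per depth).

## ISSR comparator

The comparator pipeline takes a strains × bands 0/1 matrix as given (band
calling from gels is out of scope; bands present in >95% or <5% of strains
are flagged as uninformative), computes Jaccard distances — double absence
carries no information; two all-zero fingerprints get distance 0 by logged
convention — and clusters with the same linkage machinery. The scalar
`jaccard_distance()` is hand-written as the module's contract; the matrix
path goes through `stats::dist(method = "binary")` and the two routes are
cross-checked in tests.

## The simulator: what it emulates, what it does not

`simulate_population()` generates a population with known truth so that
discovery, genotyping, similarity and titration can be validated end-to-end.
Its defaults are the study conditions this package targets: 32 strains in
two colour subpopulations (18 white, 14 gray), 12 chromosomes, ~370 marker
clusters averaging ~3.4 SNPs, 60× depth.

* **Layouts.** `"clustered"` places 2–5-SNP clusters separated by more than
  the 50-kb spacing rule, so clusters map 1:1 onto discoverable markers and
  recovery statements are exact. `"poisson"` scatters SNPs at a target
  density (default 1/104 bp) for genome-scale count checks.
* **Allele frequencies.** Ancestral frequencies are uniform on (0.15, 0.85);
  subpopulation frequencies follow a Balding–Nichols Beta model with
  divergence (Fst) 0.25 — enough structure that discovered PIC values span
  roughly 0.5–0.9.
* **Heterozygosity.** `het_rate` (default 0.9) is the probability a strain's
  two nuclear alleles are drawn independently; the complement models the
  excess homozygosity of clonal lines. No stated value exists; this one is
  chosen once as realistic for dikaryotic cultivars.
* **Pedigree.** F1 hybrids inherit one whole-cluster haplotype from each
  parent, independently across clusters — complete linkage within a 100-bp
  window, free recombination between markers. Clones are verbatim copies.
* **Engineered sharing.** `apply_sharing_targets()` operates *after*
  discovery, copying exactly `round(f·K)` marker genotypes and forcing the
  remainder to differ, so a pair's true sharing fraction is exact by
  construction. Applying `f` at the raw-SNP level instead would entangle the
  target with which windows survive PIC screening.
* **Reads.** Totals are Poisson(depth); each read picks one of the two true
  haplotypes at 1/2; bases flip independently at `error_rate` (default
  0.001). No quality scores, no mapping artefacts, no indels.

Passing tests on this generator demonstrates the *algorithms* are correct
and the thresholds behave as specified. It does not demonstrate robustness
to alignment error, reference bias, uneven coverage, or index hopping —
features of real resequencing data the generator deliberately omits.

## Numerical and testing choices

* All thresholds live in one place (`qc_thresholds()`); every boundary
  (QD = 2.0, site depth = 10/2000, DP = 10, modal fraction = 0.95,
  PIC = 0.5, spacing = 50,000, haplotype fraction = 0.10, GS = 99.00) has a
  dedicated boundary test.
* GS rounding is half-away-from-zero at two decimals; the test suite checks
  that every published-style GS value is reachable as `round(100·n/369, 2)`
  for a unique integer n.
* Test problem sizes: oracle-equivalence sweeps use 100 random ≤60-SNP
  instances plus 12 denser ones; end-to-end recovery uses 8 strains ×
  ~1,300 clusters at 60×; titration uses 20 replicates across 7 depths.
  These sizes keep the full suite near a minute while leaving the binomial
  tolerances meaningful.
* Randomness is always seeded explicitly; `sim_config()` refuses a missing
  seed rather than defaulting silently.

## Known limitations

* Haplotype counts must come from fragments spanning all SNPs of a window;
  the package defines this as an adapter contract and ships no BAM pileup
  extractor.
* GS treats every marker equally; no weighting by PIC or call confidence.
* The 0.1 haplotype-fraction rule has no error model behind it — at very
  high depth a fixed fraction threshold is conservative, at the 10-read
  floor it is permissive. The titration module exists precisely to choose a
  working depth empirically.
* Cluster trees (GS and ISSR) are exploratory summaries; no bootstrap or
  other support values are computed.
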