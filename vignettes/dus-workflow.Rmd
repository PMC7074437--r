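---
title: "Molecular DUS testing with duskit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular DUS testing with duskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duskit)
```

## The problem

Registration of a new crop cultivar requires DUS testing: the candidate must
be *distinct* from every registered cultivar, *uniform* across its plants,
and *stable* across generations. Morphological descriptors struggle when
cultivars are bred from narrow elite backgrounds; genome-wide SNP panels
from reduced-representation sequencing give a much higher-resolution
fingerprint. `duskit` implements the computational side of such a
molecular-assisted DUS assessment for inbred (selfing) crops such as
soybean:

* **Distinctness** — do the plants of each declared cultivar form their own
  cluster in a neighbor-joining (NJ) phylogeny built from genome-wide
  genetic distances, corroborated by PCA and a genomic kinship matrix?
* **Uniformity** — are there *off-type* plants (contaminant or mislabeled
  seed) sitting far outside their cultivar's within-cluster distance
  baseline?
* **Purity/stability** — what fraction of each plant's genotyped loci is
  homozygous, and which loci stay heterozygous in every plant of a cultivar?

## Data model

Genotypes are diploid biallelic SNP calls stored as alternate-allele
dosages: 0 (hom ref), 1 (het), 2 (hom alt), `NA` (missing). Dosage is a
sufficient statistic for every quantity the workflow computes (allele
frequencies, heterozygosity, distances, kinship), which is why allele-pair
strings are discarded at the VCF boundary. Positions are 1-based point loci
exactly as in VCF; chromosomes sort naturally (`chr2` before `chr10`) so
per-chromosome gap statistics are stable. SSR genotypes are unordered pairs
of fragment sizes in bp, stored sorted.

## Marker filtering

A locus enters the analysis panel when

* minor allele frequency `maf >= maf_min` (default 0.05), computed over
  called alleles only, and
* integrity (call rate) `>= integrity_min` (default 0.8).

Both rules are inclusive at the boundary; a single uniform rule is easier
to document than mixed strict/non-strict thresholds, and which convention
is used at the exact boundary is immaterial in practice. The MAF rule is a
*retention* rule — panels for fingerprinting keep polymorphic markers and
drop near-monomorphic ones, and the filter also drops loci whose MAF is
undefined because no plant was called. Whether integrity should be
evaluated per cultivar instead of over the full plant set is a defensible
design fork; `duskit` evaluates it over the full plant set, which is the
convention of standard variant-QC tools.

## Distances, trees, off-types

The SNP distance is the dosage allele-sharing distance
\[
d(i,j) \;=\; \frac{\sum_{L} |g_{iL} - g_{jL}|}{2\,n_{\mathrm{shared}}(i,j)},
\]
the p-distance on alleles: 0 for identical genotypes, 1 for opposite
homozygotes everywhere, with pairwise deletion of missing calls. Sequencing
pipelines rarely publish the exact distance their tree-building GUI used;
the allele-sharing distance is the standard, bounded, metric choice for
biallelic dosages, and a genotype-state mismatch proportion is available as
an alternative (`method = "mismatch"`). A pair of plants with *no* shared
called locus has no defined distance; this is fatal by default because a
DUS verdict must not rest on silently imputed distances
(`allow_missing_pairs = TRUE` substitutes the matrix-wide mean with a
warning).

NJ is implemented with two determinism guarantees: exact Q-criterion ties
are broken toward the lexicographically smallest pair of current node
labels (a merged node takes its smaller child label), and negative branch
lengths are clamped to zero with the deficit moved to the sibling edge so
the joined pair keeps its total length. The result is bit-reproducible
across platforms and input orderings. Trees are `ape::phylo` objects;
patristic distances (path sums) and Newick I/O go through `ape`. Bootstrap
support resamples **loci** with replacement — the universal choice for
concatenated marker panels — and annotates each internal edge with the
percentage of replicates containing the same bipartition.

Off-type classification operationalizes what an examiner does by eye on
the tree. For plant $p$ with declared cultivar $c$, let $r(p)$ be the mean
patristic distance from $p$ to the other plants of $c$. $p$ is flagged
when **both**

* $r(p) > \mathrm{median}_c(r) + k \cdot \mathrm{MAD}_c(r)$ (default `mad_k = 5`), and
* $r(p) > \alpha \cdot \mathrm{median}_c(r)$ (default `ratio_alpha = 3`)

hold. Reported off-types in real trials sit 6–12 times above the
within-cultivar average, so the defaults flag that regime with a wide
margin; the MAD rule alone would misfire on extremely tight clusters where
the MAD is nearly zero, which is why the scale-free ratio rule must also
fire. The dual rule is invariant to uniform rescaling of all distances and
to plant order, and never flags a cultivar whose plants are mutually
equidistant. Cultivars with fewer than 3 plants give no baseline and are
skipped. Within-cultivar distance summaries (max/min/average) are computed
*excluding* flagged plants, matching how such tables are reported.

Distinctness is read off tree bipartitions, not distance thresholds: a
cultivar is distinct when one edge of the unrooted tree separates exactly
its (non-flagged) plants from everything else, and a cultivar pair is
separated when some edge puts the two entirely on opposite sides. This is
scale-free and matches the cluster reading of published cultivar
phylogenies. Two selections from the same cross correctly report as
non-separated.

## Purity and stable heterozygous loci

Purity is per-plant homozygous fraction over called loci; cultivar purity
is the mean over plants, reported with min/max/sample SD in percent.
Released inbred lines go through at least six selfing generations, so
purity above 90% is the expected regime. The denominator is the plant's
*called* loci — with per-plant missingness a "all discovered loci"
denominator would conflate missingness with heterozygosity.

A locus is *stable heterozygous* in a cultivar when every non-missing call
among its plants is heterozygous and the within-cultivar call rate is at
least 0.8 (the integrity threshold reused: tolerant of sporadic
missingness, strict on zygosity). The cultivar-pair matrix of set sizes
and intersection sizes mirrors how shared residual heterozygosity is
tabulated across cultivars; under random selfing the probability that tens
of plants all stay heterozygous at the same locus is vanishingly small, so
non-empty sets indicate loci under some balancing maintenance.

## The synthetic trial generator

The real sequencing data behind published five-cultivar trials are not
deposited, so validation uses a generator that emulates their statistical
structure, with a truth table for every quantity:

* **Pedigree.** Each cultivar is a biparental cross followed by `g = 6`
  generations of single-seed descent; each plant is an independent SSD
  lineage, so a founder-differing locus is still heterozygous with
  probability $0.5^g$ and otherwise fixed to either parent with equal
  probability. The generator samples this g-step marginal in closed form,
  which is distributionally exact for independent lineages and loci and is
  the basis of the heterozygosity-decay recovery test.
* **Founders.** Cultivar "cores" diverge from a common ancestor by
  independent allele flips at rate 0.18 (two unrelated cores then differ at
  about 30% of loci, giving between-cultivar distances around 0.25–0.3);
  the two parents of a cross each diverge from their core at rate 0.02, so
  a cross segregates at about 4% of loci and within-cultivar plant
  distances land near 0.02 — the regime reported for real trials. One core
  is derived from another at rate 0.15, producing the close
  parent–offspring-like cultivar pair that must still separate.
* **The indistinguishable pair.** Two cultivars are bred from the
  *identical* founder cross with zero post-cross divergence — one line
  marketed under two names. They share their pinned stable-heterozygous
  loci too: a pair with zero post-cross divergence is the same line, and
  giving the two copies different pinned sets would smuggle in a synthetic
  distinguishing signal that the scenario is explicitly supposed to lack.
  Under the independent-SSD model a literal divergent-parent cross cannot
  produce both a genuine parent–offspring relationship and the tight
  within-cultivar clusters seen in real data (independent lineages from a
  widely segregating F1 scatter as far within a cultivar as between
  cultivars), so the parent–offspring relationship is expressed at the
  founder-core level instead.
* **Default trial shape.** 5 cultivars x 20 plants, 2000 loci on 20
  chromosomes (21,000 for the downsampling study), 8 pinned
  stable-heterozygous loci per cultivar, one off-type injected into each of
  the first two cultivars from a distant donor, 2% missingness, 0.2%
  genotyping error (hom→het or het→random hom). All sizes are chosen so
  the complete validation suite runs in well under a minute while keeping
  every distributional margin wide (off-types sit >10x the within-cultivar
  baseline, against a flag threshold of 3x).
* **Determinism.** Every stochastic stage consumes a seed derived from the
  config's master seed; the same config reproduces every output file byte
  for byte.

What the generator deliberately does **not** model: linkage/recombination
maps (every statistic in the workflow is locus-exchangeable, so linkage
adds no testable structure), read-level artifacts, allele-specific error,
and any mechanism behind stable heterozygosity (pinning is a
phenomenological stand-in). Passing tests therefore demonstrate
correctness of the statistics and decision rules under the stated
population model — not robustness to LD, batch effects, or structured
missingness in real panels.

## Numerical and degenerate-input choices

* Undefined MAF (no calls at a locus) can never pass the filter and is
  reported as its own failure reason.
* PCA mean-imputes missing dosages per locus (keeps the matrix dense
  without inventing genotypes in distance space — the distance module
  instead deletes pairwise), and fixes each component's sign by making its
  largest-magnitude loading positive, so scores are reproducible across
  platforms. Variance fractions are reported over all components and sum
  to 1.
* Kinship is VanRaden's genomic relationship
  $K = ZZ^\top / (2\sum_l p_l(1-p_l))$. Published pipelines often name a
  GUI-specific kinship ("stepwise") without a printed formula; VanRaden is
  the standard, well-defined substitute and the method tag is recorded in
  the output.
* A two-taxon NJ "tree" is the single path of the input distance; the
  final three nodes join onto one trifurcating root surrogate with the
  closed-form three-taxon lengths.
* Bootstrap replicates may lose all shared loci for a plant pair; inside a
  replicate such pairs fall back to mean imputation so the replicate tree
  stays defined.
* All child seeds (bootstrap, robustness subsets, simulation stages) are
  drawn deterministically from one master seed and recorded, so any single
  run can be replayed exactly.

## A worked run

```{r example, eval = FALSE}
library(duskit)

# simulate the default five-cultivar trial and write it as VCF + TSV
ex <- simulate_experiment(sim_config(seed = 1), out_dir = "fixture")

# full pipeline: filter -> distances -> NJ -> off-types -> distinctness ->
# purity -> het sharing -> PCA -> kinship -> manifest
res <- run_dus_pipeline("fixture/genotypes.vcf", "fixture/samples.tsv",
                        out_dir = "results", seed = 1)

res$offtypes          # two injected contaminants flagged
res$distinctness      # the shared-cross pair is the only non-separated pair
res$purity_cultivars  # ~99% purity at g = 6 selfing generations
autoplot(res$pca, sheet = res$sheet)
```

The same analysis is scriptable from a shell through the thin wrapper in
`inst/scripts/duskit` (`duskit simulate`, `duskit filter`, `duskit tree`,
`duskit run`).

## Known limitations

* The distance actually used by any given published trial is generally
  unrecoverable; verdicts here are defined relative to the allele-sharing
  distance (results are stable under the mismatch alternative for inbred
  panels, since heterozygotes are rare).
* Tree-bipartition distinctness is strict: a single stray plant inside an
  otherwise clean cluster makes its cultivar non-distinct until that plant
  is flagged and excluded. That is intended behavior for a DUS audit, but
  it means distinctness verdicts should be read together with the off-type
  report.
* Bootstrap supports are reported for inspection and are not consumed by
  the off-type classifier; the classifier uses patristic distances only.
* With cultivars of fewer than three plants neither the off-type baseline
  nor a meaningful uniformity verdict exists; such cultivars are skipped,
  not guessed at.
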