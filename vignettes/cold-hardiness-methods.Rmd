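---
title: "Methods: cold-hardiness genomics, physiology and phylogenetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cold-hardiness genomics, physiology and phylogenetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`coldhardy` bundles the quantitative methods used in a cold-hardiness
study of walnut (*Juglans*) species and their interspecific hybrids:
per-gene population-genetic selection statistics over pooled diploid
panels, a candidate-versus-background selective-sweep screen, the
electrolyte-leakage frost damage index with its field-scale winterkill
rating and ANOVA/LSD summaries, relative qPCR expression, and
alignment-free k-mer phylogenies. Because the motivating data (a
multi-species resequencing panel plus field and lab measurements)
cannot ship with a package, every analysis stage is paired with a
coalescent-based generator that produces statistically faithful
synthetic inputs, so the full pipeline is demonstrable and testable
offline. This vignette documents the models, the estimators, and the
numerical and design choices.

## Coalescent simulator

Each gene × pool genealogy is simulated under the standard Kingman
coalescent: with $k$ active lineages the waiting time to the next
coalescence is exponential with rate $k(k-1)/2$, in units of $2N$
generations. Mutations follow the infinite-sites model: each branch
receives a Poisson number of mutations with mean $\theta/2$ times its
length, and every mutation creates a new segregating site placed
uniformly (without collision) along the gene. Haplotypes are paired
into diploids in simulation order, which preserves all allele counts,
so haplotype-level expectations ($E[S] = \theta a_1$,
$E[\pi] = \theta$) carry over to the diploid panel exactly.

Three selection regimes transform the neutral genealogy:

* **neutral** — identity.
* **sweep** — with total tree height $T$ and scale $s \in (0, 1]$,
  node times map as $t \mapsto s\,T\,(t/T)^s$. This both shrinks the
  tree (less variation, as after a recent fixation) and makes it
  star-like: the concave power transform compresses old coalescences
  toward the root proportionally more than recent ones, producing the
  excess of rare variants that drives Tajima's D strongly negative. A
  plain uniform rescaling of node times was rejected during design
  because it preserves tree *shape* exactly, and Tajima's D is
  shape-driven — uniformly scaled trees have the same expected D as
  neutral ones (only fewer sites), so no choice of scale could meet
  the screen's operating characteristics. At the default $s = 0.1$
  the per-gene mean D is near $-1.8$.
* **balancing** — the root coalescence is delayed by a boost factor
  $\ge 1$, deepening the basal split and inflating
  intermediate-frequency variation, which pushes D positive (mean
  near $+0.7$ at the default boost of 5). This mimics the
  hybrid-pool signature where two diverged parental genomes meet in
  one pool; an explicit two-parent admixture mode
  (`hybrid_mode = "admixed"`) is also available.

## Population-genetic statistics

All statistics are computed per gene × pool from diploid genotypes
coded 0/1/2 (missing allowed), over the gene's interval (0-based,
half-open internally; VCF positions are converted on read).

* **Segregating sites** $S$: sites polymorphic among non-missing
  calls. A site additionally counts as a reported SNP only when its
  missing fraction is $\le$ `max_missing` (default 0.5).
* **Nucleotide diversity** $\pi$: per site,
  $2j(m-j)/\bigl(m(m-1)\bigr)$ with $j$ the derived-allele count among
  $m$ non-missing alleles — the unbiased mean pairwise difference —
  summed over SNP sites and divided by gene length for the per-bp
  value.
* **Watterson's** $\theta_W = S / a_1(n)$ per gene, with the usable
  allele count $n$ taken as the floor of the median per-site
  non-missing allele count across SNP sites (one $n$ per gene, as
  window-based implementations use).
* **Tajima's D** with the full set of constants
  ($a_1, a_2, b_1, b_2, c_1, c_2, e_1, e_2$). D is undefined in two
  distinct ways that downstream output keeps apart: `no_variation`
  ($S = 0$, serialized as `nan`) and `insufficient_samples` (fewer
  than 4 usable alleles, serialized as `NA`).
* **Observed heterozygosity** per bp: the heterozygote fraction of
  non-missing calls at SNP sites, scaled by SNP density.
* **F\_ST** across all pools jointly via the Weir–Cockerham (1984)
  variance components $a$, $b$, $c$, combined as a ratio of averages
  over segregating sites, unclamped (small negative estimates are
  reported as computed). A Hudson-style two-pool estimator is
  included as a cross-check.

## Selective-sweep screen

Candidate genes are selected by case-insensitive keyword match of
their functional labels against cold-response transcription-factor
families (DREB/DRE, ERF/EF, ICE1, ZAT, CBF). Within each pool, a
candidate is flagged as sweep-like when its Tajima's D is below
`d_threshold` (default 0) **and** both $\pi$ and observed
heterozygosity fall at or below the `percentile_threshold` quantile
(default 0.10) of the pool's random-gene background distribution.
The default percentile is set to 0.10 rather than a looser 0.25
because, on neutral candidate genes against a 200-gene neutral
background, the looser value flags about 18% of genes — an
unacceptable false-positive rate for a screen whose contract is
$\le 10\%$ — while 0.10 achieves sensitivity $\approx 0.93$ with a
false-flag rate $\approx 0.05$ at the default sweep intensity. A
Mann–Whitney candidate-versus-background contrast per pool and
statistic, Benjamini–Hochberg adjusted, complements the per-gene
calls.

## Demo panel

The built-in demo simulates nine pools — Japanese walnut (JW, 5
diploids), eastern black walnut (BW, 6), butternut (BN, 5), butternut
× Japanese hybrids (HY, 4), Arizona walnut (AW, 3), Manchurian walnut
(MW, 5), Persian walnut from Asia (PWA, 4) and from the US (PWU, 7),
and a single-genotype Northern California black walnut pool (NCB, 1).
The singleton pool is included deliberately: it exercises the
`insufficient_samples` path end to end, since no per-gene D can be
computed from a single diploid. Candidate genes (33 cold-response
loci across 10 chromosomes) evolve under the sweep regime in PWU and
under balancing in HY; all other gene × pool combinations are
neutral. Gene count, gene length (2 kb), $\theta = 5$ and the pool
sizes are package defaults chosen so the whole pipeline runs in
minutes on one CPU while keeping every statistic in a
well-conditioned regime; they are not estimates of any particular
empirical dataset.

## Physiology

The frost damage index from electrolyte leakage is
$D_I = 100\,(R_t - R_o)/(1 - R_o)$, where $R_t$ and $R_o$ are the
mean initial/final conductivity ratios of frozen and unfrozen control
samples. Ratios are averaged per replicate before differencing, which
makes the index invariant to the meter's scale. Winterkill is rated
on the 1–5 field scale by damage bands ($<5$, $5$–$20$, $20$–$50$,
$50$–$90$, $\ge 90$), with a resprouting plant capped at 4. Group
comparisons use one-way ANOVA with protected Fisher's LSD: pairwise
tests on the pooled error mean square are run only when the omnibus
F-test is significant at $\alpha$, which keeps the null
letter-splitting rate near $\alpha$; letters come from an
insert-and-absorb compact letter display.

## Relative expression

Relative qPCR expression uses the $2^{-\Delta\Delta C_T}$ method:
technical replicates are averaged within biological replicates,
$\Delta C_T$ (target minus reference) is formed per biological
replicate, and $\Delta\Delta C_T$ is taken against the calibrator
condition. The standard error of the fold change is propagated as
$\mathrm{fold}\times\ln 2\times \mathrm{se}(\Delta\Delta C_T)$. The
generator inverts this model exactly at zero noise, so round-trip
identity is testable to floating-point precision.

## Alignment-free phylogenetics

Whole sequences are reduced to sets of canonical k-mers (the
lexicographic minimum of each k-mer and its reverse complement; odd
$k$, default 25, avoids self-complementary k-mers; runs containing
non-ACGT characters are skipped). The assembly-assembly distance
between two sets is $d = -\tfrac{1}{k}\ln F$ with
$F = |A \cap B| / \min(|A|, |B|)$, capped at `d_max` (default 1.0)
for disjoint or near-disjoint sets. Trees are built by neighbor
joining (via `ape`), with tiny negative branch lengths clamped to
zero and the clamping recorded. `clade_check()` asks whether a focal
taxon falls inside the smallest split containing a named group, on
the unrooted tree, so results do not depend on an arbitrary root. A
similarity-matrix import path (distances
$1 - s_{ij}/\max s$) feeds externally computed similarity scores into
the same tree machinery.

Sequences can also be evolved along a known tree with per-branch
substitution probabilities (each must be $< 0.75$, the Jukes–Cantor
saturation bound), which is how the package engineers its
cytonuclear-discordance demonstration: twelve taxa whose nuclear
sequences place the focal butternut-like taxon with the East-Asian
clade while its organellar sequences place it with the North-American
clade.

## Determinism and numerics

Every generator takes an explicit seed; independent substreams for
each gene × pool (and each data type) are derived with a small
integer mixer (`substream_seed()`) that stays below $2^{31}$, so a
single top-level seed reproduces the entire demo byte for byte —
`run_all()` re-runs are md5-identical. Analysis stages are themselves
deterministic. Tajima's D uses the exact constant formulas rather
than approximations; $\pi$ sums unbiased per-site terms rather than
frequency squares; F\_ST accumulates numerator and denominator
separately to avoid ratio-of-ratios bias.

## Limitations

The coalescent is single-locus and panmictic per pool: no
recombination, migration or demography beyond the regime transforms.
The sweep transform is a phenomenological stand-in for a structured
sweep model; it reproduces the site-frequency-spectrum signature, not
linked-selection haplotype structure. The AAF distance saturates for
deeply diverged sequences (hence the cap), and the k-mer sets discard
copy-number information. The screen's operating characteristics are
calibrated at the default $\theta$ and panel sizes; very small pools
(fewer than two diploids) never yield D and are reported, not
flagged.
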