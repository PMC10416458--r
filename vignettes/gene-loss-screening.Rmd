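---
title: "Synteny-aware screening for genes lost at an evolutionary stage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synteny-aware screening for genes lost at an evolutionary stage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synteloss)
```

## The problem

Phenotypic capabilities are sometimes lost in evolution together with the
genes that support them: a classic example is the loss of appendage
regeneration in amniotes, which fish and amphibians largely retain. Finding
the genes whose disappearance coincides with the loss of a trait requires
deciding, for every protein-coding gene of a well-annotated *reference*
species, whether an ortholog exists in each species of a panel straddling
the transition: *lower* taxa that branched off before it, *middle* taxa in
which the trait is reduced, and *upper* taxa that lack it. `synteloss`
implements that decision de novo, from proteomes and gene coordinates alone
— deliberately not from curated ortholog databases, whose assignments the
screen is meant to second-guess — and combines it with a
differential-expression (DE) filter so that the surviving genes are both
lost at the right stage and active in the process of interest.

## The model

### Homology weights

Every pair of proteins $x, y$ receives a raw local-alignment score
$s(x,y)$ (Smith–Waterman, BLOSUM62, affine gaps at the blastp defaults of
open 11 / extend 1, a gap of length $k$ costing $11 + k$). Raw scores are
length-dependent, so they are normalized against the self-alignments:

$$w(x,y) = \frac{2\,s(x,y)}{s(x,x) + s(y,y)}.$$

The weight is dimensionless and usually lies in $[0,1]$; it is not clamped,
because local alignment can in rare cases push it slightly above 1. The
denominator may alternatively be the smaller or the larger self-score
(`norm = "min"` / `"max"`), which gives largely equivalent orderings; the
mean is the default. Pairs are kept as matrix cells only when they would be
reported as hits (E-value at most 0.1); an absent cell *is* the statement
"raw score 0, E-value infinite". The matrix is symmetrized — larger raw
score and smaller E-value win, one-sided cells are mirrored — before
weights are computed, so $W$ is exactly symmetric, which the backward check
below relies on.

Gene-level weights project the protein matrix through the
protein-to-gene map: $W(X,Y) = \max\{w(x,y) : x \in X,\, y \in Y\}$, the
maximum over encoded isoform pairs (an optional protein filter can restrict
which isoforms participate, e.g. by length or domain content). For each
gene and each target species, only the top `u` homologs above the weight
and E-value thresholds are retained — the *table of homologs* — and each
entry carries its `rank` (position in the query's per-species list) and
`back_rank` (position of the query in the target's reciprocal list, or
infinity when absent). Rank 1 with back-rank 1 is the bidirectional best
hit (BBH).

### Forward and backward checks

A candidate ortholog $X'$ of reference gene $X$ must pass two tests.

The **forward check** confirms local synteny: at least
`witnesses_required` pairs of *witness* genes $(Y, Y')$ must exist, with
$Y$ in the neighborhood of $X$, $Y'$ in the neighborhood of $X'$, and the
pair satisfying the witness-homology condition (by default BBH, stricter
than the top-`u` condition that qualified $X'$ itself). A neighborhood is
every gene whose interval intersects the focal gene's interval padded by
`radius` on both sides, on the same chromosome or scaffold; orientation
is ignored, and a gene on an unplaced scaffold simply has a small
neighborhood. The default radius of 5 Mbp is motivated by the size range
of topologically associating domains, within which transcriptional
control — and hence selective pressure on gene order — is concentrated.

The **backward check** guards against paralogs. $X'$ is rejected when the
reference species holds another gene $U$ that is itself a table homolog of
$X'$, has local synteny with $X'$ (the same forward check, run with $U$ in
the reference role), and is closer to $X'$ than $X$ is by more than a
threshold:

$$W(X', U) - W(X, X') > \lambda, \qquad \lambda \in [0, 1].$$

$\lambda = 0$ is the plain check; the inequality stays strict so that an
exact tie — two genes equally similar to $X'$, plausibly co-orthologs —
never rejects. Because rejection only becomes harder as $\lambda$ grows,
each individual presence call is monotone non-decreasing in $\lambda$;
aggregate list sizes shrink only *almost* monotonically because different
genes flip at different thresholds. A quotient variant compares raw-score
ratios instead, $S(U,X')/S(X,X') > \lambda_1$ with $\lambda_1 \ge 1$.

Candidates are tried in decreasing weight order; the first to pass both
checks is the called ortholog, and a gene whose candidates all fail is
*absent* in that species. At most one ortholog per species is ever
reported — the method prefers a defensible single call over one-to-many
mappings.

### Group screening and lists

Presence calls are tallied per configured species group (the m/n/p/q
bookkeeping: counts of primitive mammals, birds, reptiles and fish
retaining the gene, when the groups are set up that way). Screens are
boolean *metaconditions* over atoms `present_in(group, k)` — true when the
gene is present in at least `k` species of the group — combined with
`and`, `or`, `not`. The grammar is a restricted R expression; only those
operators and atoms are accepted, so a config file cannot smuggle in
arbitrary code. The canonical screens are:

* **list-1** — present in a lower group, absent in every upper group;
* **list-2** — genes from the DE table with FDR below `fdr_max` (strict,
  matching the usual "FDR < 0.01" convention) and $|\log FC|$ at least
  `theta_min` (a lower limit, hence non-strict);
* **list-3** — the intersection, ordered by descending logFC;
* **list-4** — the list-3 genes additionally absent from every middle
  group;
* **final list** — list-4 after the three-species filter.

The machinery is symmetric: pick the reference from the upper group, swap
the roles, and the same code screens for genes that *emerged* at the
stage instead.

### The three-species condition

A reference gene can look lost in the uppers while a lower-species
ortholog of it still has a perfectly good upper ortholog — typically when
an ancestral duplication was resolved differently in different lineages.
Such a gene is not truly eliminated. For each gene $X$ in list-4, each
lower species $F$ (other than the reference) and each radius $r_i$
(defaults 1, 2, 5 Mbp), the filter finds the ortholog $X^*$ of $X$ in $F$
and asks whether $X^*$ has an ortholog in any upper species, running
the same forward/backward machinery with $F$ in the reference role and
radius $r_i$ on both links of the chain. The flag for $r_i$ is 0 when such
a chain exists; genes whose flags are 0 at *every* radius are excluded.
Keeping this in a separate pass (rather than inside the main presence
call) makes the excluded genes inspectable. Genes with no lower-species
ortholog at all are vacuously safe.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `u` | 3 | homologs kept per (gene, species); a dynamic cut-off — the closest database homolog is often not the ortholog, so more than one candidate must survive to the synteny stage |
| `weight_min` | 0.07 | weight threshold for table entries (strict >) |
| `e_value_max` | 1e-7 | E-value threshold for table entries (strict <) |
| `radius` | 5 Mbp | neighborhood half-width, per species overridable |
| `witnesses_required` | 1 | witness pairs demanded by the forward check |
| `beta` | BBH | witness-pair homology condition |
| `lambda` | 0 | backward-check weight gap (difference variant) |
| `lambda1` | 1 | raw-score ratio (quotient variant) |
| `radii` | 1, 2, 5 Mbp | three-species condition radii |
| `fdr_max` | 0.01 | DE significance threshold (strict <) |
| `theta_min` | 0 | effect-size floor on \|logFC\| (non-strict) |

## What the simulator emulates — and what it does not

`simulate_dataset()` generates an ancestral genome of random peptides
(lengths 60–90 by default, residues drawn from BLOSUM62-style background
frequencies) laid on chromosomes at a fixed spacing of 500 kb, so the
standard 5 Mbp radius spans about ten genes on either side and radius
boundaries fall in predictable places. Each species is derived by applying
planted losses, per-residue substitutions (sampled proportionally to
$e^{\mathrm{BLOSUM62}}$ within the row, so conservative replacements
dominate), optional nearby paralog duplications with extra divergence,
optional truncated second isoforms, and optional local order shuffles.
Planted three-species chains are built the honest way: an ancestral
duplication whose copies survive asymmetrically (reference keeps both,
uppers keep only the diverged copy, lowers keep only the original, middles
neither), which reproduces the backward-check rejection pattern the filter
exists to catch. Every emitted gene has a truth entry, and
`oracle_presence()` — a from-scratch exhaustive reimplementation of the
entire decision path that shares only the pairwise aligner with the
pipeline — provides the independent reference the pipeline is tested
against.

The simulator deliberately does not model indels, codon structure, rate
heterogeneity across sites, gene conversion, or realistic intergenic
distance distributions. Passing tests therefore demonstrate algorithmic
correctness (the implementation computes the defined quantities exactly,
agrees with brute force, and recovers planted structure), not calibrated
performance on real genomes, where annotation errors and assembly
fragmentation are the dominant error sources.

## Numerical and design choices

* **E-values on the built-in aligner path** are a Karlin–Altschul-style
  surrogate $E = K m n e^{-\lambda S}$ with the gapped BLOSUM62/11/1
  constants. Thresholding, ranking and BBH depend only on score ordering,
  which the surrogate preserves; when exact BLAST E-values matter, the
  precomputed score-table input path carries the producer's values
  verbatim.
* **Tie-breaking** everywhere is (descending weight, ascending E-value,
  ascending gene id), which makes ranks, BBH and therefore whole runs
  deterministic and byte-reproducible.
* **Boundary rule**: neighborhood membership is interval intersection
  with the padded window, inclusive at the boundary; coordinates are
  1-based inclusive.
* **Witness multiplicity**: a witness gene serves at most one pair per
  check; with more than one witness required, pairs are matched greedily
  in descending weight order rather than by maximum bipartite matching —
  at the default of one witness the two coincide.
* **Within-species entries**: a gene's own self-pair is excluded from its
  table bucket (it would uselessly occupy rank 1), but paralog entries
  within a species are kept — the backward check's search for $U$ needs
  them.
* **Thresholds apply uniformly** before any ranking, to forward lists and
  reciprocal (back-rank) lists alike; table-bucket membership is what
  "homolog according to the matrix" means operationally, for candidates
  and for the backward check's $U$.
* **Both links of a three-species chain** are evaluated at the same
  radius $r_i$, the simplest consistent reading; the per-radius flags make
  any alternative easy to recompute.
* **Per-direction top-u retention**: an entry can survive in one
  direction while its mirror is truncated away; the reciprocal list then
  simply reports an infinite back-rank. This keeps truncation local and
  is what makes the back-rank an informative annotation rather than a
  constraint.
* **Degenerate inputs**: genes without proteins get no table entries and
  are therefore absent everywhere; empty buckets are absences, not
  errors; an empty DE table empties list-3 onward without failing.

## Problem sizes

The test suite runs entirely on simulated data generated at test time:
oracle-equivalence sweeps use 20 scenario configurations of 14–16 genes
across 4 species (about 60 genes and 300 pairwise presence decisions per
configuration), algebraic properties use a 5-species × 50-gene matrix
(≈ 63,000 protein pairs), and the λ-sweep covers 51 (gene, species) cases
at 21 λ values. These sizes were chosen so that the exhaustive oracle —
which is quadratic and enumerates every witness pair — remains the
bottleneck rather than the pipeline, while still exercising paralog
confounders, shuffled synteny and boundary-radius witnesses.

## A complete run

```{r, eval = FALSE}
groups <- list(
  fish = list(species = c("fish1", "fish2"), role = "lower"),
  amph = list(species = "frog", role = "lower"),
  rept = list(species = "liz1", role = "middle"),
  mamm = list(species = c("mam1", "mam2"), role = "upper"))

sim <- simulate_dataset(sim_config(
  groups, reference = "frog", genes_per_genome = 18, divergence = 0.04,
  loss_events = list(list(genes = c("g004", "g011"),
                          groups = c("rept", "mamm"))),
  chain_genes = "g007", seed = 1))

refg <- sort(sim$dataset$genes$gene_id[
  sim$dataset$genes$species_id == "frog"])
de <- simulate_de_table(refg, c("g004_frog", "g007_frog", "g011_frog"),
                        seed = 2)

res <- run_screen(sim$dataset, de,
                  species_groups(groups, "frog"), sl_params())
res$final$gene_id   # the planted clean losses; the chain gene is filtered
```

## Known limitations

* The built-in aligner keeps one best local alignment per pair; there is
  no multi-HSP handling, and no composition-based score adjustment.
* Presence calls return at most one ortholog per species; co-ortholog
  sets are visible only indirectly, through ties protected by the strict
  backward inequality.
* DE statistics are consumed, not computed: the package expects an
  edgeR/DESeq2-style table and makes no attempt to re-derive it from
  counts.
* The surrogate E-value is not a BLAST E-value; with the default
  thresholds this only matters for borderline hits near `e_value_max`,
  and a precomputed score table sidesteps it entirely.
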