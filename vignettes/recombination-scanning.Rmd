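---
title: "Detecting and removing recombination signals with recscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and removing recombination signals with recscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recscan)
```

## The problem

Recombination and reassortment move blocks of sequence between viral (and
bacterial) lineages. A recombinant genome violates the single-tree
assumption underlying most phylogenetics-based molecular-evolution
analyses, so before such analyses one usually wants to (i) find the
recombinant sequences and the breakpoints of each transferred fragment,
(ii) decide which apparent signals are artefacts, and (iii) emit a version
of the alignment from which the recombinant signal has been removed.
`recscan` implements this workflow as a scriptable R package with a
command-line front end, so it can sit inside a pipeline with no
interactive verification step.

## The scan statistic

The detector examines every triplet of sequences \((a, b, c)\). A column
is *triplet-informative* when all three residues are unambiguous,
ungapped bases and exactly two of them agree (a 2-vs-1 split); the
agreeing pair is the column's *pattern* (`ab`, `ac` or `bc`). Under
clonal evolution with independent sites, the pattern sequence along the
informative positions of a triplet is an i.i.d. multinomial draw whose
proportions reflect the triplet's topology. Recombination breaks that
homogeneity: inside a transferred fragment the recombinant pairs with the
donor lineage, producing a run in which one pattern dominates.

A window of `window` informative sites (default 30) slides along the
profile with step 1. For each pattern \(q\), the in-window count \(m\) is
compared with a binomial null,
\[
p_{\mathrm{raw}} \;=\; \sum_{k=m}^{n} \binom{n}{k}\hat p^k (1-\hat p)^{n-k},
\qquad n = \texttt{window},
\]
where \(\hat p\) is the proportion of pattern \(q\) among all informative
sites of the triplet *excluding the current window*. The leave-window-out
estimate keeps a long foreign tract from inflating its own background. A
Haldane-style continuity correction (half a success and one trial added to
the background) keeps \(\hat p\) strictly inside \((0, 1)\), so
\(p_{\mathrm{raw}}\) can never degenerate to 0 when every pattern-\(q\)
site sits inside the window.

Windows are retained when \(p_{\mathrm{raw}} \cdot F < \alpha\) with the
family-wise Bonferroni factor \(F = \binom{n_{\mathrm{seq}}}{3} \times\)
(window placements in the triplet) by default (`triplets_x_windows`); the
`triplets_only` mode is available for power studies. Scanning in
informative sites rather than alignment columns makes the window's
information content, and hence the test's sensitivity, comparable across
divergence levels.

## Demarcation and attribution

Overlapping significant windows for the same pattern are merged. Inside a
transferred fragment every informative site must support the donor pair
(the recombinant's residues there *are* the donor's), so the fragment
appears as one uninterrupted pattern run. The demarcated region is
therefore the maximal contiguous pattern run anchored at the most
significant window of the merged group. Chance occurrences of the pattern
just outside the tract extend that run by a geometric number of sites with
mean \(p/(1-p)\) per edge; that expected overshoot is trimmed. Breakpoints
are then placed midway between the outermost in-region site and the
nearest flanking informative site supporting a background pattern
(`demarcate_breakpoints`); where no flanking site exists, the alignment
terminus is used and that breakpoint is excluded from downstream
breakpoint statistics as truncated rather than observed.

Which member of the in-region agreeing pair is the recombinant is decided
by the *identity-change* discriminator: the member whose identity to the
third triplet member changes across the region boundary is the one
carrying foreign sequence, while the untouched member's identity to the
third is flat. We adopted this rule after finding that the simpler
partner-switch reading (the member shared by the inside and outside
agreeing pairs) systematically misattributes events to the donor whenever
the true recombinant sits on an isolated lineage with no close relative in
the triplet; the partner-switch reading is retained as the tie-break. When
the outside majority pattern equals the in-region pattern there is no
switch to read at all; the odd member out is then reported and the event
is marked `ambiguous_recombinant` in its method string.

Events from different triplets that name the same recombinant and overlap
reciprocally by at least 50% are consolidated by union-find, and the
lowest corrected-p member represents the group. Triplets that contain the
recombinant but not the donor still produce genuine signal and are
reported under their own recombinant names; an exhaustive scan of a
one-event dataset therefore usually lists the true event first (it has by
far the smallest p) followed by weaker echoes, which is why downstream
surgery operates on the consolidated table rather than assuming one row
per biological event.

## False-positive vetting

Processes other than recombination — rate variation among sites and
lineages, convergent mutation, and above all misalignment — can fabricate
pattern runs. Each event is vetted on its neighbourhood (the triplet plus
its `k = 5` nearest neighbours by global identity, over the region padded
by one region-length on each side):

* **PHI** (`phi_test`): the mean *refined incompatibility* over all pairs
  of parsimony-informative sites within `w = 100` columns of each other.
  The pair score is \(E - V + C_c\) on the bipartite state graph — the
  minimum number of extra mutations any tree must invoke — whose
  correctness is enforced in the test suite by an exhaustive-parsimony
  oracle over all unrooted topologies rather than assumed. The permutation
  null shuffles informative-column contents while keeping positions fixed
  (1000 permutations by default; the p-value uses the add-one rule, so it
  is bounded below by \(1/(n_{\mathrm{perm}}+1)\) and equals 1 when
  `n_perm = 0`). An event whose neighbourhood shows *no* distance-
  dependent incompatibility (\(p > \alpha\)) is flagged `phi_suspect`.
* **Four-gamete** (`hudson_kaplan_rm`): biallelic site pairs exhibiting
  all four gametes, reduced by deleting intervals that contain another and
  counted greedily by right endpoint — the classic lower bound
  \(R_m\). If no incompatible pair straddles either breakpoint, the event
  is flagged `four_gamete_suspect`.
* **Misalignment heuristic**: gap fraction across the triplet within the
  region above 0.3, or overlap with a run of 15+ consecutive columns that
  are each at least half gapped, flags `misalignment_suspect`. This is a
  declared gap-density heuristic, not a reconstruction of any particular
  program's procedure.

Suspect-flagged events are excluded from dataset surgery by default.

## Breakpoint-distribution tests

With an annotation (GFF3 or a GenBank FEATURES table, both converted to
0-based half-open alignment coordinates), breakpoint counts are tested
against a null that places breakpoints independently and uniformly over
all columns, under three labelling schemes: coding vs non-coding, per
gene (overlaps resolved to the nearest gene start, recorded in the
output), and gene edges vs interiors (`edge_frac = 0.1` of each gene
length per terminus; the fraction is configurable because no canonical
definition of "edge" exists). The per-label p-value is two-tailed by
distance from the null mean with Benjamini–Hochberg adjustment across
labels. The uniform null is deliberate and transparent; an alternative
restricting the null to detectable positions can be emulated by masking
columns before testing, and both breakpoints of an event are counted
unless `collapse_per_event` is chosen.

## Dataset surgery and gene extraction

Four recombination-free outputs: `strip_recombinants` (drop recombinant
rows), `mask_recombinant_fragments` (replace event regions with `N` —
missing data, not a deletion, so distance and likelihood methods treat
the fragment as unknown), `split_recombinants` (backbone plus one row per
event; backbone and parts partition the original row exactly), and
`partition_alignment` (cut at unique breakpoints; concatenating the
partitions reproduces the input byte for byte). All are idempotent for a
fixed event table. `extract_gene_alignments` splices CDS intervals in
transcription order, reverse-complements minus-strand genes, honours the
phase of the first interval, trims trailing partial codons and removes —
column-synchronized across all rows, so the output stays aligned — any
codon in which some row carries a frame-shifting 1- or 2-gap pattern;
columns expressed in two reading frames can be excluded.

## The simulator

`simulate_clonal` draws a Yule tree (`ape::rphylo`), rescales branches so
the mean root-to-tip path equals `mean_divergence` (expected
substitutions/site), and evolves sequences under Jukes–Cantor with
multiple hits allowed (`phangorn::simSeq`); discrete-gamma rate
heterogeneity (4 categories) is available to reproduce the
rate-variation confounder that motivates the vetting tests.
`implant_events` copies donor columns into an acceptor post hoc, so
ground truth is exact by construction. The simulator emulates clonal
backbones and clean mosaic transfers; it does **not** model indels,
alignment error, within-region post-transfer mutation, or
coalescent-with-recombination genealogies, so passing tests demonstrate
correct behaviour under the stated model, not robustness to misalignment
or ancient recombination.

Study conditions used by the test suite and the acceptance script, chosen
once as representative of small virus datasets: clonal calibration runs
use 10–20 taxa, 2–5 kb, mean divergence 0.05; mosaic-recovery runs use 10
taxa, 10 kb, one 1500-column event between parents at p-distance ≥ 0.10
on trees of mean divergence 0.15, with the sensitivity ladder at parent
divergences 2/5/10% on trees 1.5× as deep; the end-to-end
scan–mask–rescan control uses 12 taxa, 5 kb. Per-event vetting in the
large replicate loops uses 500 permutations (p resolution 1/501, ample
for a 0.05 threshold); the single-event default stays at 1000.

## Numerical and design choices

* Coordinates are 0-based half-open internally, 1-based inclusive in
  every file and report.
* IUPAC ambiguity codes count as missing data everywhere; treating them
  as partial matches would inflate identity in noisy data.
* `max_missing_frac = 0.2` per column for exclusion, matching common
  phylogenetic masking practice.
* JC distances saturate at `cap = 5.0` substitutions/site when
  \(p \ge 0.75\); pairs with no comparable columns are `NA` with a
  warning.
* Trees are neighbour-joining on JC distances. Maximum-likelihood
  inference is deliberately not performed: NJ keeps the tool
  dependency-light and exactly testable (additive matrices must be
  recovered with Robinson–Foulds distance 0), and users wanting ML can
  feed the emitted partitions to an external tool. Negative NJ branches
  are clamped to zero with the deficit moved to the sister branch.
* All tie-breaks are deterministic (pattern order `ab < ac < bc`, smaller
  begin, lexicographic names), so identical input and configuration give
  byte-identical outputs; the CLI writes a run manifest to make that
  checkable.

## Limitations

Only the triplet scan is implemented as the detection engine; the many
complementary detectors found in full recombination-analysis suites
(GENECONV-, bootscan-, chi-square- or likelihood-based) are out of scope,
as are circular-genome wrap-around breakpoints, ML/Bayesian trees, and
any network access. Query-vs-reference naming tags (`[Q]`, `[R:group]`)
are this package's own declared grammar. Sensitivity degrades gracefully
with parent divergence — at 2% divergence a 1.5 kb fragment carries only
a few dozen informative sites — and the misalignment flag is a heuristic:
regions flagged as suspect deserve inspection, not automatic deletion.
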