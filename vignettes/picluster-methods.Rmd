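---
title: "Methods: comparative piRNA-cluster discovery and evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative piRNA-cluster discovery and evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picluster)
```

This vignette explains the models and procedures `picluster` implements,
the parameters that matter, the numerical choices made where a
specification was genuinely open, and what the synthetic-data tests do
and do not establish about real data.

## Coordinates and input model

All coordinates are 0-based half-open (BED convention), everywhere. WIG
input is 1-based and is shifted on read; nothing downstream ever sees a
1-based coordinate. This single-convention rule is deliberate: the
pipeline chains many interval operations (exon partition, window
tilings, extensions, overlap fractions), and mixed conventions are the
classic source of off-by-one drift.

Coverage tracks are sparse per-base counts for one strand of one
library. Counts are read 5'-end tallies by default, because cluster
calling is read-count based, not base-cover based; a `count_mode`
attribute records the alternative pileup interpretation where a source
provides it. The library size used for RPM normalization
(RPM = count × 10⁶ / library size) is always supplied externally (a
mapping log, the simulation manifest) and never inferred from a track:
a per-strand file is a subset of the library, and inferring the
denominator from it would silently inflate RPMs.

## Genic piC calling

For each gene, exonic bases are partitioned exactly into 5'UTR, ORF and
3'UTR with respect to strand. Non-coding transcripts (thickStart ==
thickEnd) carry all bases in the 3'UTR slot so that their whole length
is assessed by the same rule; the ncRNA curation filter then removes
them by identifier pattern, mirroring how such records are handled in
practice.

Annotated 3'UTRs frequently miss the real transcript end, so the caller
extends the 3'UTR (and, for reporting, the 5'UTR) in windows of
2000 bp (mammals) or 500 bp (Drosophilids): a window is appended when it
holds at least 1 RPM of same-strand reads, and extension stops at the
first failing window, at the next same-strand annotated gene, at the
contig end, or after `max_windows` (default 5). Iterating the window
rather than applying it once is a design choice: a single fixed bump
cannot capture 3'UTR ends that run several kilobases past the
annotation, while the per-window 1 RPM condition and the cap keep the
growth bounded and auditable. The same-strand-neighbor stop applies the
rule used elsewhere in the pipeline for 3'UTR padding. The 5'UTR
extension is computed but plays no part in retention, which is a 3'UTR
criterion only.

A gene is retained when its same-strand 3'UTR density is
≥ `genic_min_rpm` (10 RPM; the twice-as-stringent mode uses 20), with the
threshold inclusive. Genes with ≥ 50 RPM on the ORF are flagged
`orf_retained`.

The curation step quantifies what is otherwise a manual grooming pass.
Two of its rules needed thresholds that no specification states
numerically: a candidate is removed as repeat-confounded when at least
`te_frac` (default 0.5) of its 3'UTR signal lies in annotated repeat
intervals, and as neighbor-sourced when at least `neighbor_frac`
(default 0.5) lies inside another same-strand gene body. Both fractions
are exposed as arguments and recorded in the output so the step is
reproducible; every removal carries a reason code.

## Intergenic piC calling

The genome is tiled in 5 kb windows. A cluster opens at a window whose
combined-strand density exceeds 1 RPM (strict), extends while windows
hold at least 1 RPM, closes below it, and is kept when its total is
≥ 10 RPM. Two choices here were open and are config-exposed:

* **Step size.** "Sliding" windows without a stated step are
  implemented as a non-overlapping tiling (step = window size), which
  makes calls deterministic and matches the 5 kb decomposition used by
  the strand index. A consequence worth knowing: the tiling is anchored
  at coordinate 0, so calls are translation-invariant only for shifts
  that are multiples of the window step (the property tests use such
  shifts).
* **Strand combination.** Both strands are summed for detection, since
  intergenic clusters may be single- or dual-stranded; per-strand
  densities are retained for the index.

Terminal partial windows are included with their actual counts.
Clusters overlapping called genic loci are flagged (optionally dropped);
intergenic discovery on real data should also be read together with the
genic calls, since a highly expressed genic 3'UTR necessarily lights up
its window.

Intergenic loci have no gene name to root them across species, so each
cluster is keyed by the ordered pair of reference-rooted names of its
nearest non-overlapping flanking genes within 1 Mb (`max_anchor_dist`);
equal keys across species declare syntenic orthologs. One-sided anchors
at contig edges are flagged rather than matched.

## Strand-configuration index

Per 5 kb window, with A and B the plus- and minus-strand densities,

$$ I = \frac{(A-B)^2}{A^2+B^2} \in [0, 1], $$

averaged (unweighted) over the cluster's windows. The index is
scale-invariant — counts or RPMs give the same value — symmetric, 1 iff
exactly one strand is occupied, 0 iff the strands balance exactly.
Windows with A = B = 0 leave the formula undefined; they are excluded
from the mean rather than imputed, because either imputation (0 or 1)
biases the average, and their count is reported. A `zero_policy`
switch scores them 0 for sensitivity analysis.

## Cross-species comparison

piC repertoires are matrices of RPM over reference-rooted locus names;
a locus joins the Venn subset of species where it reaches
`min_rpm` (10, or 20 in stringent mode). mRNA profiles are compared on
housekeeping-normalized RPKM ratios (RpL32/Rp49), which removes
platform and depth effects and makes levels comparable across species:
pairs are shared within 3-fold (|Δlog₁₀| ≤ 0.5), triples when
SD(log₁₀) ≤ 0.3; the stringent criteria are 0.3 and 0.177.

Two open points required decisions:

* A locus qualifying for more than one pair but not the triple is
  assigned to the pair with the smallest log₁₀ difference (precedence
  triple > pairwise > singleton), keeping the partition a partition.
* A locus expressed in several species but similar in none is assigned
  to the singleton of the species where it is most expressed. Both
  rules are deterministic with lexicographic tie-breaks.

Partitions are compared by a Pearson chi-square over the subset-count
vectors (no Yates correction, so the 2×2 statistic equals the classical
closed form) plus per-subset pooled two-proportion Z tests, Bonferroni
multiplied by the number of subsets and capped at 1. When any expected
cell falls below 1 the chi-square is unreliable: a warning is raised,
`exact_flagged` is set, and a Fisher exact p-value is attached.

ECpiC/LCpiC classification uses a per-clade quorum: ECpiC iff expressed
in at least `min_species_per_clade` (default 1) species of *every*
clade. The quorum default is the weakest rule consistent with
"conserved across the three Eutherian clades"; it is an argument, and
the per-clade evidence counts are emitted with every call so any
stricter quorum can be applied post hoc.

## Gain/loss inference

Presence/absence characters (expressed ≥ threshold or not) are
reconstructed on a dated, rooted tree by Wagner parsimony: bottom-up
Sankoff cost propagation with costs gain_cost (0→1) and loss_cost
(1→0), then top-down state choice. Defaults are 1:1 costs — plain
Wagner parsimony; asymmetric costs are supported but not default, since
nothing in the method's provenance fixes a ratio. Two tie-break rules
are fixed and documented: at the root, ties go to *absent*, consistent
with the inference that ancestral piC repertoires were small; below the
root, ties go to the parent's state (no event). Both choices attain the
minimum cost; they only select among equally parsimonious histories.
Per-branch events divided by branch lengths (MY) give gain and loss
rates, reported both raw (events/MY) and per character.

The synthetic generator plants histories that are *uniquely* minimal:
gains on branches whose subtree misses at least one clade, and losses
of whole clades whose complement is not itself a single subtree
(otherwise a lone gain is equally parsimonious and per-branch recovery
would be ill-posed). This is a property of the test design, not of the
inference.

## Conservation scores, controls, targets

Interval score averaging sums per-base values (phastCons, phyloP) over
segments and divides by base length. Bases missing from the track count
as 0 by default — the convention of genome-wide phastCons dumps, where
absence means unconserved — with an `exclude` mode for phyloP, where 0
is not neutral. Both the raw per-base mean and the per-segment
length-normalized view are derivable from the output.

Negative-control genes are drawn (seeded) at 3× the number of genic piC
loci from expressed genes producing no piRNAs, and their 3'UTRs are
padded within the clade range (mouse 500–1100 bp, fly 250–500 bp)
toward the piC mean 3'UTR length, truncated at same-strand neighbors.

The antisense target screen reports all maximal exact
reverse-complement matches of ≥ 13 nt between piRNAs and transcripts.
Exact matching replaces a short-query BLAST heuristic whose effective
criterion is that same 13 bp of complementarity; whether the original
tolerated mismatches inside the span is unstated, so the conservative
exact model is the default and a mismatch mode is reserved in the
interface.

## The synthetic-data generator

`simulate_scenario()` emulates a multi-species testes/ovary small-RNA
study: nine species in three clades on an ultrametric tree (clades
joined around 90 MY), 200 genes per species in conserved 1:1 orthology
and synteny, designated genic piC loci at 50 RPM of same-strand 3'UTR
reads over a 0.2 RPM background, syntenic intergenic clusters of three
5 kb windows at 300 RPM — the expression scale of major piC loci — in
labeled single- or dual-stranded configuration, piRNA lengths on a
triangular 24–31 nt law peaking at 26 nt, and an 80% 5'-uridine bias.
Read counts are Poisson, positions uniform within the target region —
the simplest placement satisfying the RPM contracts. Cross-species mRNA
levels share a per-gene base level with 0.1 decades of log-normal
noise. All randomness flows from one seed; two runs with the same
config are byte-identical.

What the generator deliberately does not model: transposon landscapes
and repeat-derived piRNAs, ping-pong biogenesis signatures, hotspot
(non-uniform) read placement, annotation errors, and partial orthology.
Consequently, passing recovery tests show that the callers, the index,
the classification and the parsimony machinery implement their rules
exactly and recover clean planted truth; they do not show robustness to
repeat confounders or annotation noise, which on real data is exactly
what the curation filters and the genic-overlap flag exist to absorb.
Read sequences are drawn i.i.d. (with the 5' bias) rather than copied
from a materialized genome, since no pipeline stage re-aligns them;
target-search fixtures construct complementary sequence pairs
explicitly.

## Problem sizes used in the checks

The automated checks run at sizes chosen to exercise every rule while
completing quickly: recovery on 5 species × 200 genes with 20
designated genic and 8 intergenic loci; strand-configuration recovery
on 200 simulated clusters; oracle equivalence on 100 random coverage
tracks, 1000-locus Venn partitions, and exhaustive parsimony
enumeration on 20 random trees of up to 6 leaves × 200 characters; the
conservation round trip on the full 9-species, 3-clade scenario.

## Known limitations

* `expression_overlap()` implements the pairwise/triple criteria for 2
  or 3 species, as defined; larger sets need a chosen trio
  (`run_pipeline(compare_species = ...)`).
* Synteny anchoring keys on the ordered flanking pair and will not
  match clusters across large inversions that swap the flanks.
* The intergenic caller's fixed tiling can split a cluster straddling a
  window boundary with sub-threshold edge windows; the window trace is
  emitted so such cases can be inspected.
* Wagner parsimony reports one minimum-cost history under documented
  tie-breaks, not the full set of optimal reconstructions.
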