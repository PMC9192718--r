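---
title: "Surveying clustered ubiquitin-ESCRT systems in archaeal genome sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying clustered ubiquitin-ESCRT systems in archaeal genome sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

Asgard archaea — the prokaryotic lineage closest to eukaryotes — encode
homologues of large parts of the eukaryotic ubiquitin-coupled ESCRT
membrane-remodelling machinery: ubiquitin and its E1/E2/E3 enzymes and
deubiquitinases, ESCRT-I components (Vps23/37, Vps28), ESCRT-II components
(Vps22/36, Vps25), ESCRT-III, and the Vps4 ATPase. In prokaryotes, genes
that work together tend to sit together, so a basic comparative question is:
across a set of genomes from one phylum, how often does each *pair* of these
functional roles occur within a single compact genomic neighborhood?

`escrtscan` implements that survey as a reusable, fully testable pipeline:

1. **Catalogue** — classify each genome's proteins into the twelve
   ubiquitin/ESCRT functional categories using a diagnostic table of
   InterPro domain accessions, fusion-aware.
2. **Co-location** — for every category pair, the fraction of genomes in a
   set in which the pair co-locates within a bounded window.
3. **Synteny** — extract the genomic regions around catalogued genes and
   link genes across genomes by reciprocal best hits (RBH).
4. **Alignment preparation** — gap-threshold trimming/filtering and
   multi-marker supermatrix concatenation feeding phylogenomic inference
   (the tree inference itself is out of scope).
5. **Protein properties** — sequence-derived molecular weight, A280
   extinction coefficients, and SEC calibration-curve fitting, the
   calculations that back mass-based oligomer assignments.
6. **Simulation** — a seeded generator of genome sets, ortholog families
   and alignments with known ground truth, so every stage is testable
   without downloads.

## The co-location statistic

For genomes $g = 1..n$ in a set and categories $a, b$, define per genome a
tri-state: *absent* if either category has no catalogued gene; *colocated*
if some gene of $a$ and some gene of $b$ lie on the same contig inside a
region shorter than the window $w$; *coexisting only* otherwise. The
reported cell is

$$\hat f_{ab} = \frac{\#\{g : \text{colocated}\}}{\#\{g : \text{both present}\}},$$

with an `NA` cell when the denominator is zero. Three deliberate choices:

* **Denominator = coexisting genomes, not all genomes.** This makes a
  never-coexisting pair (`NA`, rendered white in heatmaps) a different
  state from a pair that coexists but never clusters (fraction 0). With an
  all-genomes denominator the two would be indistinguishable.
* **Distance = minimal containing region, strictly below the window.**
  "Within less than 10 kb" is read as: the smallest contiguous region
  covering both genes is $< w$ bp (default $w = 10\,000$). The
  alternative nearest-edge-gap reading is available via
  `colocation_config(measure = "gap")`; the two differ by the lengths of
  the genes themselves. The survey literature does not always say which is
  meant, so both are implemented and the region reading is the documented
  default.
* **Fusion genes co-locate by themselves.** A single gene whose protein
  carries diagnostic domains of two categories (e.g. a Vps23/37–Vps28
  fusion) is maximal co-location, counted when
  `count_fusion_as_colocated = TRUE` (default). On the matrix diagonal,
  two *distinct* genes are required — a gene cannot co-locate with itself.

Strand is ignored throughout: the statistic is purely positional.

```{r}
library(escrtscan)
sim <- simulate_genome_set(sim_config(seed = 11, n_genomes = 20))
catal <- catalogue_simulation(sim)
m <- colocation_matrix(sim$genome_ids, catal, set_id = "demo")
m$fraction[1:4, 1:4]
```

## The diagnostic domain table

The default table (`default_diagnostic_map()`) maps 21 InterPro accessions
onto the 12 categories; each accession belongs to exactly one category and
a protein's category set is the union over its hits. Classification is
idempotent under hit duplication and applies no extra e-value filter —
domain annotation pipelines already threshold their matches. The composite
ESCRT-I signature IPR037202 ("Vps23/37/28") is kept as its own category by
default because it is diagnostic of the fused architecture; for co-location
purposes `expand_composite = TRUE` converts it into evidence for both
Vps23/37 and Vps28. The table is plain data and can be exported, edited and
re-loaded, since InterPro signatures drift between database releases.

## Synteny regions and reciprocal best hits

Regions are drawn `flank_bp` (default 2000) beyond each catalogued gene's
boundaries — boundary-based flanks, not midpoints, matching how gene-arrow
synteny plots bound their panels — clipped at contig boundaries
(`clipped_left`/`clipped_right` record truncation), and merged when
windows overlap or abut. Every emitted region contains at least one
catalogued gene and no two regions on a contig overlap; re-merging emitted
regions is a fixed point.

RBH uses the standard recipe: keep hits with e-value strictly below
`evalue_max` (default 1e-5, so a tie at exactly 1e-5 is excluded), take
each query's best subject by bitscore with deterministic tie-breaking
(higher bitscore, then lower e-value, then lexicographically smaller
subject id), and emit mutual bests. External BLAST tabular files are the
fidelity path; for self-contained tests `pairwise_similarity()` provides
Smith–Waterman local alignment under BLOSUM62 with affine gaps (open 11,
extend 1) via `Biostrings`, converted to bit scores with the standard
gapped Karlin–Altschul constants ($\lambda = 0.267$, $K = 0.041$) and to
e-values as $mn\,2^{-S'}$. Those constants are fixed approximations — the
built-in scorer is for linking synthetic or small datasets, not for
reproducing BLAST statistics.

## Alignment hygiene and the supermatrix

All thresholds follow a strict reading of "over X% gaps": a column (or
sequence) is removed only when its gap fraction is *strictly greater* than
the threshold, so a 50% column survives trimming at 0.5 and a 60% sequence
survives filtering at 0.6. The presets in routine use are 0.5 and 0.9 for
columns and 0.6 for sequences (applied after column trimming). Only `-`
counts as a gap (`.` is normalised to `-` on read); ambiguity codes X/B/Z
are residues. Trimming is idempotent and never reorders surviving columns.

`concatenate_markers()` builds a supermatrix over a configurable ordered
marker list — typically a set of 15 ribosomal proteins encoded in
co-locating genes; the identity of that set follows whichever curated
marker panel the user adopts, which is why the list is an argument rather
than a constant. Genomes present in fewer than `min_markers` (default 5)
marker alignments are excluded and reported; missing markers are padded
with gap runs of the marker's alignment length; the partition table
(RAxML-style on export) records each marker's 1-based column interval.
Concatenation conserves each genome's residue count. Genomes absent from a
marker's alignment count that marker as missing, while fragmentary
sequences count as present — no length floor is imposed.

## Protein properties

`molecular_weight()` sums average isotopic residue masses plus one water
(18.01528 Da), matching the ProtParam convention used when comparing to
SEC/MALS estimates; monoisotopic masses sit behind a flag.
`extinction_coefficient_280()` uses the Pace coefficients
($5500\,n_W + 1490\,n_Y + 125\,n_{\text{cystine}}$); cysteines are assumed
reduced by default and the oxidized variant pairs them as
$\lfloor n_C/2 \rfloor$ cystines. The mass-basis coefficient (absorbance
of 1 mg/ml) is molar over molecular weight. SEC calibration fits
$\log_{10}(\text{mass, kDa})$ on $V_e/V_0$ by ordinary least squares; a
sensible column gives a negative slope, and `apparent_mass()` inverts the
line in closed form. The six-protein calibration kit (29–669 kDa) ships as
`sec_standards()`; elution volumes are column-specific and must be
measured, which is also why a published apparent mass cannot be recomputed
without the corresponding standard elution volumes.

## What the simulator emulates — and what it does not

`simulate_genome_set()` plants, per genome, one gene per category; with
probability `cluster_presence_prob` (default 0.7) the genome carries the
genes in one compact cluster, otherwise they are scattered with at least
`scatter_spacing_bp` (15 kb) between them, i.e. never co-locating under a
10 kb window. Gene lengths are uniform on 400–800 bp and in-cluster
intergenic gaps uniform on 20–150 bp: a full 12-gene cluster then spans
about 8 kb (standard deviation about 0.4 kb), so all pairwise spans stay
below 10 kb with overwhelming probability — the degenerate "everything in
one cluster" genome observed in the most complete assemblies is
reproducible by construction. Fusions (default probability 0.1 per
adjacent cluster pair) emit one gene carrying both categories'
accessions, mirroring the fused ESCRT-I architectures seen in
Heimdallarchaeota. Contig fragmentation (a break planted inside the
cluster) is off by default — the default genome is closed — and is an
opt-in stressor emulating metagenome-assembled genomes. Decoy genes carry
reserved `IPR9xxxxx` accessions disjoint from the diagnostic table, so
accidental diagnostic collisions are impossible.

Randomness is streamed per genome (and per family) from the master seed,
so growing `n_genomes` never perturbs earlier genomes, and emitted files
are byte-identical across runs. Ortholog families are a root sequence with
i.i.d. per-site substitutions per genome copy (`ortholog_mutation_rate`,
default 0.05); `simulate_msa()` realises requested per-column or
per-sequence gap fractions *exactly*, which is what makes the boundary
semantics of trimming testable.

The simulator deliberately does **not** emulate: realistic sequence
evolution (indels, rate heterogeneity, codon structure), nucleotide-level
genome sequence, operon strandedness, paralogy, or annotation error.
Passing tests on simulated sets therefore demonstrate the correctness of
the counting, merging and thresholding rules — not robustness to noisy
real-world annotation, which should be assessed on real genomes.

## Numerical and scale choices

Internally all genomic coordinates are 1-based inclusive (the GFF3
convention); BED export converts to 0-based half-open. Removed-column
indices are reported 1-based, as is natural in R. All threshold
comparisons that encode "less than"/"over" wording are strict
inequalities, and every tie-break in RBH selection is deterministic, so
identical inputs give identical outputs on any platform. The test suite
exercises the co-location estimator at 200 genomes (where the planted
fraction 0.7 is recovered within the three-sigma binomial band
$3\sqrt{0.7 \cdot 0.3 / 200} \approx 0.097$), oracle equivalence on 50
random sets of at most 5 genomes and 15 genes against plain brute-force
enumeration, and RBH against mutual-argmax enumeration at up to 20
proteins a side — sizes at which exhaustive enumeration is exact and fast.

## Known limitations

* The catalogue is only as good as the diagnostic table; homologues whose
  domains fall below the annotation pipeline's own thresholds (e.g.
  divergent Vps23/37 homologues recognisable only by alignment) are
  missed. The table is user-replaceable for exactly this reason.
* The built-in aligner's e-values are approximate (fixed Karlin–Altschul
  constants, no composition adjustment); use real BLAST tables when
  statistics matter.
* One published comparison cannot be recomputed offline: the printed
  monomer/dimer masses and extinction coefficient of the Heimdallarchaeota
  Vps22 homologue require its Uniprot sequence, which is not
  redistributable here; the corresponding check runs whenever a local copy
  of that sequence is provided under `inst/extdata/`.
* Co-location significance testing is out of scope: the pipeline reports
  raw fractions, as the survey design calls for, without a null model for
  gene-order randomisation.
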