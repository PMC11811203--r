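---
title: "Methods: sort-seq deep mutational scanning and regulatory target calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sort-seq deep mutational scanning and regulatory target calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thapscan)
```

`thapscan` is a desk-scale re-implementation of the computational core of a
FACS sort-and-sequence deep mutational scan (DMS) of a transcription factor
driving a fluorescent reporter, in the style of the THAP1/PSMB5 system: a
THAP-family zinc-finger factor whose activity at a proteasome-subunit
promoter is read out as GFP fluorescence, with cells sorted into a
GFP^dim^ (factor inactive) and a GFP^bright^ (factor active) bin. Because
the wet-lab screen cannot be re-run at a desk, the package pairs every
analysis stage with a generative simulator that plants known truth, so the
whole pipeline can be exercised and validated end to end.

This vignette records the models, the tunable parameters and the design
choices that were genuinely open. It states no empirical result beyond what
the package's tests and acceptance script themselves compute.

## Library design

`design_library()` enumerates a codon-level site-saturation library. The
mutagenised region (all residues except the initiator methionine) is
partitioned greedily left-to-right into segments of at most `tile_length`
residues (default 36, which maps a 213-residue protein onto six segments:
2–37, 38–73, 74–109, 110–145, 146–181, 182–213). Each position receives
exactly one construct per amino acid — 20 per position, including the
wild-type control — for 212 × 20 = 4240 constructs on a 213-residue
protein. Segments are pooled pairwise for screening (three pools of two
segments), and each construct is represented by the full DNA sequence of
its mutagenised segment, with one designated (human-preferred) codon per
amino acid.

Two points were genuinely open and are resolved as package policy:

* **Wild-type control distinguishability.** Twenty constructs per position
  include the wild-type amino acid, but a wild-type construct built from
  the reference codon is sequence-identical to every other wild-type
  construct of its segment. Under the default
  `wt_control_policy = "synonymous_recode"`, each control carries the
  alphabetically first synonymous codon differing from the designated one,
  so it remains individually countable. Methionine and tryptophan have no
  synonymous alternative; their controls fall back to the reference codon
  and collapse — within a segment — onto a single index key, which the
  counting stage tallies once as a collision group.
* **Coordinates.** Residue coordinates are 1-based inclusive throughout,
  matching the "residues 2–37" convention of the field.

`build_reference_index()` maps every distinct segment sequence to the
variant ids sharing it; the index also records, per key, which codon was
edited — structure the read matcher exploits (below).

## The generative screen model

### True activity landscape

`simulate_landscape()` assigns each variant a latent activity on the
wild-type = 1 scale. Wild-type controls are exactly 1; every substitution
at a *critical residue* (defaults are analogues of the four zinc-chelating
positions 5, 10, 54, 57) is exactly 0. All other substitutions draw from a
four-component mixture conditioned on the structural class of their
position: `inactive` (0), `intermediate` (Normal(0.5, 0.15)), `neutral`
(1) and `enhancing` (Normal(1.3, 0.1)), truncated to [0, 1.5]. The default
region map mirrors a THAP-family factor — zinc finger 2–81, disordered
linker 82–138, a four-residue cofactor-binding motif 134–137 overriding
the linker, coiled-coil 139–191, disordered C-terminus 192–213 — with
intolerant-heavy mixtures in the structured regions, a ~90%-inactive
mixture in the cofactor motif, and neutral-heavy mixtures in the
disordered regions. The point masses at 0 and 1 give the screen
unambiguous planted-inactive and planted-active classes for recovery
checks; the weights are a scientific judgement call, fixed once, and make
the simulated heatmap qualitatively resemble a real scan of a two-domain
factor.

### Sorting and sequencing

`simulate_sort_seq()` models, per pool and transduction replicate:

1. **Library composition**: per-variant abundance weights are log-normal
   (`abundance_sigma` = 0.5), drawn once per pool — the plasmid pool is
   shared by both replicates; replicates differ in infection, sorting and
   sequencing only.
2. **Infection**: integrations are Poisson with MOI 0.3; a cell with at
   least one integration expresses a single variant (single-copy
   assumption at low MOI). Only the infected count matters, so it is drawn
   as one binomial. The default cell number is auto-sized so that expected
   coverage is 200 infected cells per variant, the coverage floor a
   practitioner would maintain; a warning is raised below 200-fold.
3. **Fluorescence and gating**: a cell carrying activity *a* fluoresces at
   `fluor_base + a * dynamic_range + Normal(0, noise_sigma)` in log10
   units (defaults 1.0, 2.0, 0.3), and is sorted dim below `gate` (default
   2.0, midway) or bright at or above it. Wild type (activity 1) sits a
   full decade above the gate. Per-variant bin counts are drawn by
   binomial thinning with `p(bright) = pnorm((mu - gate)/noise_sigma)` —
   exactly equivalent to simulating each cell and gating it, without
   materialising millions of cells. The single-log-scale linear map is the
   simplest monotone fluorescence model consistent with a dim/bright sort.
4. **Sequencing**: `reads_per_bin` reads (default 200,000 per
   pool × replicate × bin, about 140 per variant per bin — modest for a
   production short-read run) are drawn multinomially over the bin's
   cells. Each read is `flank5 + segment insert + flank3` (15-bp constant
   flanks) with i.i.d. substitutions at `read_error_rate` (default 0.001);
   indels and PCR bias are out of scope. An empty bin yields a warning and
   an empty FASTQ, not an error.

What this simulator does *not* emulate: PCR jackpotting, index hopping,
paired-end overlap, gate spillover/doublets, and epistasis with expression
level. Passing recovery tests therefore demonstrates the scorer's
correctness under the stated noise model, not robustness to every failure
mode of a real screen.

## Read counting

`tabulate_counts()` reduces each FASTQ (named
`pool<i>_rep<j>_<dim|bright>.fastq`) to per-variant counts. Flanks are
matched as read prefix/suffix with up to `max_flank_mismatch` (default 2)
substitutions each; the insert between them is looked up in the index
exactly, and otherwise — with `max_insert_mismatch = 1` — rescued to the
*unique* key at Hamming distance 1. Ties are `ambiguous`; inserts whose
length matches no key, or with no key within reach, are `unmatched`;
unlocatable flanks are `no_flank`. The accounting identity
`assigned + ambiguous + unmatched + no_flank = input` holds exactly per
file and is asserted in the tests.

Because every index key is the segment reference with one codon replaced,
rescue does not need a scan over 4000+ keys: the read is diffed against the
segment reference once, and only keys whose edited codon can absorb the
observed differences (at most a handful) are checked. A generic
brute-force Hamming matcher handles arbitrary small indices and serves as
the independent oracle in the tests. The 0/1-mismatch contract replaces a
general-purpose aligner deliberately: inserts are fixed-length designed
sequences, so exact-plus-unique-rescue is both faster and easier to reason
about than alignment. Reads are treated single-ended (the read covering
the mutagenised segment); a read matching another segment's key is counted
for that segment.

## Scoring, filtering and downstream summaries

For each normalisation scope — one pool × replicate, since pools are
sequenced as separate amplicons — the raw enrichment of variant *v* is the
pseudocounted frequency ratio

$$ e_v = \frac{(b_v + c)/\sum_w (b_w + c)}{(d_v + c)/\sum_w (d_w + c)},
\qquad c = 0.5, $$

and the normalised score is $s_v = e_v / \overline{e}_{\mathrm{WT}}$, the
arithmetic mean over the scope's wild-type controls, so the wild-type mean
is exactly 1 in every scope (asserted to 10⁻⁹). Scores are reported
unclamped; values above 1 represent enhanced activation. Two filters
follow, with thresholds that the original screen left unstated and that
are package policy: a variant is `recovered` if its dim+bright reads reach
`min_reads_per_replicate` (default 20) in *every* replicate, and
`discordant` if recovered but its replicate scores differ by more than
`concordance_delta` (default 0.5, maximum pairwise difference). Retained =
recovered and concordant; the bookkeeping 4002 recovered − 179 discordant
= 3823 retained = 90.2% of 4240 is reproduced arithmetically by
`summarize_filters()`.

One intrinsic limitation is worth stating: once a variant's activity is
high enough that essentially all its cells sort bright, its dim count
approaches zero and its enrichment is dominated by abundance rather than
activity. Scores therefore saturate above the gate, and orderings *within*
the fully-active class are not meaningful. This — and gating stochasticity,
not sequencing depth — is what bounds the rank agreement between true and
estimated activities in the end-to-end check.

`activity_matrix()` arranges retained mean scores on the position × 20
grid with missing cells enumerated (collapsed Met/Trp control groups
cannot be placed in a single cell and stay missing).
`compare_structure_classes()` splits positions at a pLDDT-style confidence
threshold (default 60) and compares per-position mean scores with a
two-sided rank-sum test: exact enumeration (with midranks) when both
classes have ≤ 10 positions — `wilcox.test`'s exact path refuses ties,
and all-tied classes are the norm here — and a tie-corrected normal
approximation without continuity correction otherwise.
`classify_patient_variants()` calls a listed variant `impaired` when its
mean score is strictly below the threshold (default 0.5, i.e. below 50% of
wild type; a score of exactly 0.5 is `active`), reporting non-retained
variants as unclassifiable.

## Co-essentiality mining

`pairwise_coessentiality()` ranks partners of a query gene by plain
Pearson correlation of effect-score profiles over pairwise-complete cell
lines (≥ 3), ties broken lexicographically. The bias-corrected/whitened
correlations of dedicated co-essentiality pipelines are intentionally not
reproduced; plain Pearson is transparent and sufficient for ranking a
strong partner. Dependent lines are counted strictly below the effect
threshold (default −0.25); lineage enrichment of a line selection uses the
hypergeometric upper tail (the original analysis did not name its test;
hypergeometric is the natural choice for a selection-vs-universe count).

The companion simulator plants a gene module sharing a latent per-line
factor and a "rescue" covariate: the query gene's effect is
`base + beta * z(expression) + loading * factor + noise`. Defaults
(loading 0.2, base −0.55, beta 0.15, noise 0.2, 1100 lines, 15% immune
lineages expressing the bypass paralog highly) were calibrated so the
planted matrix reproduces the printed marginal structure of the motivating
screen: a module correlation near 0.5, roughly 85% of lines dependent at
the −0.25 threshold, and strong immune enrichment among non-dependent
lines. The closed-form attenuation r = loading²/(loading² + σ²) for a
two-gene module is verified by simulation in the tests.

## Regulatory target calling

`scan_thabs()` scans both strands for the THABS consensus `TNNNGGCA`
(N = any base), reporting 0-based half-open coordinates on the plus
strand. "Near-perfect" is operationalised as exactly one mismatch at a
non-N position. One convention needed fixing: an `N` in the *subject*
matches nothing and counts as a mismatch even under a wildcard — an
ambiguous base is absence of evidence, not a match. Because this
convention differs from IUPAC-set matching, the scanner is a small
shifted-comparison implementation of its own, checked against a naive
per-window oracle in the tests.

`call_de()` is deliberately minimal: log2 counts-per-million with a 0.5
pseudocount, per-gene Welch t-test on the log scale, Benjamini–Hochberg
adjustment, and significance at FDR < 0.001 with fold change ≥ 2. It
stands in for a full RNA-seq workflow at desk scale; externally computed
DE tables with the same columns can be fed to the downstream steps on real
data, and the contribution here is the thresholding/discounting/
intersection logic, not the test statistic. For qPCR follow-up,
`delta_delta_ct()` implements 2^(−ΔΔCt) against a reference gene and
calibrator sample; group comparisons on its output are a plain `t.test()`
away. `discount_control_effects()` removes genes significant in the
control-vs-untransduced contrast at the same thresholds before target
calling, and `call_direct_targets()` intersects the surviving significant
genes with promoter occupancy — any peak overlapping ±1000 bp of the
strand-aware TSS, the window being a parameter since "proximal promoter"
is not a quantified term.

The RNA-seq simulator plants three truths — knockout-only DE genes (220
down, 57 up by default), transduction artifacts shifted in both
sgRNA-carrying groups (30), and promoter-occupancy flags (42 of the DE
genes) — mirroring the qualitative 277/220/57/42 structure of the
motivating dataset, which is not desk-reproducible and is treated as
structure, not as target numbers. Planted-truth recovery (artifact
removal, exact direct-target set) is asserted under a *deep-counts*
configuration — six replicates per group, dispersion 0.02, |log2FC| ≥ 3,
baseline ~2000 counts — chosen by power analysis so the weakest planted
gene sits at |t| ≈ 25 on ~10 df, far beyond the BH cut-off near 3 × 10⁻⁵;
with the default shallow design (3 replicates, dispersion 0.08, effects
from 1.5-fold) a 3-vs-3 t-test simply lacks the power for exhaustive
recovery at FDR < 0.001, which is a property of the test, not a defect of
the implementation.

## Problem sizes, determinism and numerical notes

* Every simulator takes a `seed` and is byte-reproducible under it; the
  acceptance script derives all its seeds from one `--seed` flag.
* The end-to-end acceptance run uses the full default screen: 4240
  variants, 3 pools × 2 replicates × 2 bins, ~1.1 M cells per pool and
  200,000 reads per bin (2.4 M reads total). Unit tests use a miniature
  two-segment design (480 variants) so the suite stays fast.
* Degenerate inputs are contracts, not crashes: empty bins warn and write
  empty FASTQs; empty FASTQs tabulate to zero columns; a scope without
  wild-type controls, a gene with no effect scores, mismatched DE
  universes, or an all-`NA` annotation are rejected with named errors.
* With pseudocount 0 an all-dim variant has infinite enrichment;
  the default 0.5 keeps scores finite, and per-bin rescaling invariance
  holds exactly at c = 0 and asymptotically (within 1% at counts ≥ 10⁴)
  otherwise.

## Known limitations

Substitution-only sequencing errors; single-read (not paired) matching;
two-bin sorting only (no multi-bin gradient scoring and no Bayesian/EM
enrichment estimator); no codon-level (synonymous) effect analysis; plain
Pearson co-essentiality; the minimal DE caller described above. The
default 213-residue protein is a deterministic synthetic sequence — sized
and structured like the motivating factor but not any natural protein —
so positional results on it are illustrative, not biological.
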