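---
title: "Methods: family mining, domain divergence and co-expression networks"
author: "florafam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family mining, domain divergence and co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(florafam)
```

# Scope

`florafam` implements a complete desk-scale analysis of a plant MIKC-type
MADS-box transcription-factor family: mining candidate family members from
nucleotide unigenes, collapsing redundant unigenes, classifying members into
the twelve canonical MIKC clades (AP1/FUL, AP3/PI, AG, SEP, SOC1, SVP, AGL6,
AGL12, AGL15, AGL17, FLC, BS), quantifying MADS-domain divergence and
selection pressure, summarising qRT-PCR expression, and building
family-anchored co-expression networks with a density-minimising Pearson
correlation threshold. Every input can be generated synthetically with known
ground truth, so each stage is validated against planted signal rather than
against irreproducible external data.

This vignette records the modelling choices, their assumptions, and the
numerical conventions, in the order the pipeline runs them.

# Family mining

## Six-frame translation

Unigenes are unoriented and often fragmentary, so all six reading frames are
translated: frames +1..+3 read the forward strand at offsets 0..2, frames
-1..-3 read the reverse complement likewise. Trailing partial codons are
dropped, stops are kept as `*`, and any codon containing `N` translates to
`X`. Initiator-codon special-casing is disabled — a frame window is not an
ORF, so `CTG` must translate as leucine even at position 1.

## Position-specific log-odds domain scan

The MADS domain is ~60 residues and essentially indel-free across the
family, which makes a full profile HMM (with insert/delete states)
unnecessary at this scale. The scanner instead uses an ungapped
position-specific score matrix built from a set of equal-length seed blocks:

$$\mathrm{score}(j, a) \;=\; \log_2
  \frac{(c_{ja} + \kappa\, b_a)/(n + \kappa)}{b_a}$$

with per-column counts $c_{ja}$, background frequencies $b_a$ (uniform by
default), and pseudocount weight $\kappa = 1$. A window of profile length is
scored as the sum of its column scores; windows containing `*` or `X` are
skipped. This is a deliberate, documented simplification of an HMM search:
it is fully specifiable, oracle-testable, and requires no external binary.
What is lost is tolerance to indels inside the domain.

The acceptance threshold is a fixed fraction (default 0.6) of the maximum
attainable profile score. The rationale: profile bit-scores scale with the
information content of the seed set, so an absolute threshold does not
transfer between profiles, while a fixed fraction of the maximum does. At
0.6, planted domains mutated at 5% per site are accepted essentially always,
while random 60-mers score far below zero on average (most non-consensus
residues have log-odds near $-\log_2(n+1)$), giving an empirical decoy hit
rate of effectively zero — both properties are enforced by the test suite.

Within a transcript, overlapping hits are resolved by keeping the single
best-scoring window over all six frames (ties: smaller start, then frame
order +1, +2, +3, -1, -2, -3), matching one-domain-per-unigene usage.

## Redundancy removal

Unigene sets contain redundant fragments of the same transcript. These are
collapsed CD-HIT-style: sequences sorted by length descending (ties by id),
each joining the first established representative with identity at or above
`tau_id` (default 0.90), otherwise founding its own cluster. Identity is
defined over the optimal local alignment (match +1, mismatch -1, gap -2 per
position) as matched positions divided by the length of the shorter
sequence. CD-HIT's k-mer prefilter is an efficiency device, not part of the
definition, and is omitted at desk scale; alignment is delegated to
`Biostrings::pairwiseAlignment`. The two inputs are put in canonical order
before alignment so identity is exactly symmetric.

# Clade classification

The reference analysis would align full-length proteins (MAFFT E-INS-I) and
build approximate-ML trees (FastTree). Both steps are replaced by anchored
60-column domain blocks compared by p-distance, with neighbor joining for
tree output. The substitution is recorded as such: it is self-contained and
oracle-testable, at the cost of ignoring K- and C-domain signal, which in
real data carries part of the clade separation.

* **p-distance**: differing positions / compared positions, with positions
  carrying `X` in either sequence excluded from both counts.
* **Neighbor joining**: standard Saitou–Nei with the Q-criterion. Ties in Q
  are broken by the lexicographically smallest pair of node labels (internal
  nodes carry the smaller child label), so the topology is a deterministic
  function of the input. Negative branch lengths are clamped to zero at
  serialisation. On additive matrices the algorithm provably recovers the
  generating topology; the tests check this on random 5–8-taxon trees and
  against `ape::nj` as an independent implementation.
* **Classification** uses a nearest-reference vote (`m = 3`) on p-distance
  rather than tree placement: the NJ tree is emitted for inspection, not
  used for assignment, because a k-NN vote has an unambiguous tie policy
  (smallest nearest distance among tied labels, then the label of the single
  nearest reference) and degrades gracefully with panel size.
* **Family acceptance**: the source analysis separated true MIKC-type hits
  from other MADS-box hits "by further phylogenetic analysis" without a
  stated criterion. Here the rule is explicit and configurable: accepted if
  the voted label is not the outgroup label and the nearest-reference
  distance is at most `d_accept` (default 0.4, roughly the between-clade
  distance of the synthetic panel).
* **Paralog pairs** are mutual nearest neighbours within one species at
  p-distance at most `d_max` (default 0.15). "Closely related" is not
  quantified in the source; 0.15 over a 60-residue domain (≤ 9 differences)
  is a conservative reading, and the parameter is exposed.
* **Orthologs** are reciprocal best hits under score = −p-distance, ties by
  id order.

# Domain divergence and selection

## Per-site divergence and lineage-specific residues

Per alignment column, the divergence rate is the fraction of differing
unordered sequence pairs among comparable pairs (`X` excluded pairwise).
A column is *lineage-specific* for residue $r$ when every focal-group
sequence carries $r$ and no other-group sequence does. Columns are numbered
1-based from the first profile column, the convention in which sites such as
K25/N33/F58 are reported for B-class MADS domains.

## Ka/Ks (Nei–Gojobori 1986)

The selection statistic is the NG86 counting method with Jukes–Cantor
correction — the standard fully specified counting approach, chosen because
the source does not name its method. Conventions that matter:

* Synonymous site counts per codon are the fraction of the nine
  single-nucleotide changes that preserve the amino acid, averaged over the
  two sequences. Changes that would create a stop codon are counted as
  nonsynonymous, so $S + N = 3 \times \#\mathrm{codons}$ holds exactly — an
  invariant the tests assert on every pair.
* Codons differing at $d$ positions are resolved by averaging the
  synonymous/nonsynonymous step counts over all $d!$ mutational pathways
  that avoid stop codons; if every pathway is blocked (possible only in
  pathological inputs) the average falls back to all pathways.
* $d = -\tfrac{3}{4}\ln(1 - \tfrac{4p}{3})$ is undefined at $p \ge 3/4$;
  `ng86_kaks()` raises an error by default or returns `NA` under
  `on_undefined = "na"`, and `clade_mean_kaks()` reports the number of
  undefined pairs rather than dropping them silently.
* $\omega = d_N/d_S$ is undefined when $d_S = 0$ (reported as `NA`, counted).

Because codon blocks come from domain hits, the alignment is ungapped by
construction and no codon-alignment step exists. Whether a clade-level Ka/Ks
is a pairwise mean or another summary was unstated in the source; the
arithmetic mean over defined pairs is used. The implementation is validated
against a second, independently coded NG86 (recursive pathway enumeration)
on 1,000 random 60-codon pairs at $10^{-10}$.

# Expression statistics

* **Relative expression** uses the $2^{-\Delta C_t}$ method with three
  reference genes. The combination rule across references is not stated in
  the source; the arithmetic mean of the reference Ct values is used, which
  equals the geometric mean of their linear quantities — the standard
  multi-reference normalisation. No calibrator sample is involved (this is
  $\Delta C_t$, not $\Delta\Delta C_t$).
* **Not detected** is an explicit mask propagated through every step, never
  an imputed zero: a zero would fabricate an infinite fold change.
* **Stage fold changes** average replicates per stage first, then compare
  each stage with its predecessor as $r = v_s / v_{s-1}$, reported signed:
  $r$ if $r \ge 1$, else $-1/r$, so $|FC| \ge 1$ and the sign is the
  direction. Transitions from masked or zero stages are flagged undefined.
  (Computing per-replicate ratios first and averaging was the alternative;
  stage means were chosen as the simpler estimator given three biological
  replicates.)
* **Clustering** uses correlation distance $1 - r$ with average linkage,
  the common default of expression heatmap tools when the linkage is
  unstated; genes are sorted by id first so the result is input-order
  invariant, and constant genes are excluded with a warning because $r$ is
  undefined for them.
* **Detection** uses a threshold of 1 (FPKM-like units) by default: a gene
  is detected if any sample reaches it, a clade if any member gene does.

# Co-expression networks

The network procedure is the package's centrepiece and follows five steps.

1. **DE screening.** A two-sided Welch t-test per gene between vegetative
   and reproductive samples, retaining genes at `p < alpha` (default 0.05)
   with *no* multiple-testing correction — this is a screening step that
   determines which genes enter the correlation analysis, not an inferential
   claim, and the source's retained-gene count is likewise uncorrected.
   Testing is done on `log2(x + 1)`: FPKM-like values carry multiplicative
   noise, and on the log scale the t-test is calibrated (the tests verify a
   rejection rate of 0.05 ± 0.01 on 10,000 null genes). Degenerate genes
   with zero variance in both groups get `p = 1` when means agree.
2. **PCC matrix** across all samples, on the same `log2(x + 1)` scale.
   Whether the source restricted samples per class is unstated; all samples
   are used.
3. **Threshold training.** For each candidate threshold on a grid (0.50 to
   0.99 by 0.01) the graph with edge rule $r \ge \tau$ is built and its
   density $D = 2E / (N_c (N_c - 1))$ computed **over the non-isolated
   nodes** $N_c$. The trained threshold minimises $D$; ties go to the
   largest threshold (the sparsest graph). Defining density over the whole
   gene universe would make $D$ monotone in $\tau$ and the optimum always
   the top of the grid; a trained *interior* optimum is only meaningful when
   isolated nodes are excluded, which is therefore the interpretation
   adopted. Intuitively the minimum sits where many genes still participate
   but only through their strongest partners — below it, bulk
   moderate correlations flood in; above it, only tight near-clique cores
   survive and density rises again.
4. **Edge rule.** Co-expression only ($r \ge \tau$) by default; an
   absolute-value rule ($|r| \ge \tau$) is available as an option for
   analyses that want anti-correlated regulation in the same graph.
5. **Module extraction.** The family genes, their direct neighbours, and
   only edges incident to at least one family gene are kept; modules are the
   connected components of this star-union subgraph. This matches the
   source's extraction ("family nodes with their adjacent connections") and
   its arithmetic: an adjacent gene's degree inside the subgraph *is* its
   number of family connections, which is what the ≥2/≥4/≥5 connectivity
   tallies count. Hub structure is reported as per-family-gene degree.

Tissue-specificity calls use the detection threshold: vegetative-specific
means detected in at least one vegetative sample and in no reproductive
sample (and symmetrically); the source's rule is unstated, so the simplest
threshold rule is used and the threshold exposed. Term enrichment is the
exact hypergeometric upper tail per term with Benjamini–Hochberg adjustment
across terms; terms with no annotated background gene are skipped.

# The synthetic data generator

The generator emulates the statistical structure the analysis assumes, with
known ground truth:

* **Transcriptomes.** Positives embed a back-translated copy of a 60-residue
  consensus, mutated at a per-site rate (default 0.05), at a random strand,
  frame and offset inside random flanks; decoys are random sequence.
  Back-translation takes the alphabetically first codon per residue, so a
  planted protein maps to exactly one nucleotide block. Frame and offset are
  recorded, which is what lets the tests demand recovery *at the planted
  coordinates*, not merely anywhere.
* **Expression.** Log2 expression is
  $\mu_g + s_g\,\delta_g\,x_{\mathrm{grp}} + \sigma(\sqrt{\rho}\,z_s +
  \sqrt{1-\rho}\,\varepsilon_{gs})$ with $x_{\mathrm{grp}} = \pm 1/2$ for
  reproductive/vegetative samples; expression is its power of two, hence
  positive with multiplicative (log-normal) noise. A single latent factor
  $z_s$ per module gives a closed-form within-module population correlation
  of exactly $\rho$ — the property the correlation tests lean on. The
  default design is 6 vegetative + 7 reproductive samples, mirroring a
  13-tissue floral study; validation runs raise this to 20 + 20 to control
  correlation sampling noise, which is a statement about the synthetic
  conditions, not about any external dataset.
* **Background structure.** Non-module DE genes get shift $\pm\delta$
  (default $\delta = 4$, i.e. 16-fold — strongly organ-biased genes) with
  random sign, producing a bulk of same-direction correlations around
  $\delta^2/(\delta^2 + 4\sigma^2) = 0.8$; module genes get a smaller shift
  (default 1.5) plus their latent factor at $\rho = 0.9$, i.e. population
  correlations near 0.94. A few near-duplicate cliques (default five groups
  of four at $\rho = 0.999$) emulate fragmented unigenes of one transcript,
  which real unigene sets always contain. This layering is what gives the
  density profile its interior minimum — bulk edges flood in below it,
  near-duplicate cliques keep density high above it — so the trained
  threshold lands strictly inside the grid, cleanly below the module
  fragmentation point, and the two planted modules (one vegetative-high,
  one reproductive-high, so no background gene can bridge them) are
  recoverable. These defaults were fixed from the latent-factor algebra
  before validation and are not tuned per run.
* **Ct tables.** $C_t = a - b\,\log_2(x + 1) + \eta$ with $a = 40$ cycles,
  $b = 1$ cycle per log2 unit (amplification efficiency 2), noise 0.15
  cycles; reference genes are set to constant expression so their Ct is
  stable by construction, and Ct above 40 is masked as not detected. At zero
  noise the map is exactly invertible, which the round-trip tests exploit.
* **Annotation.** One designated term is assigned to module genes at an
  elevated rate (default 0.8) and to the rest at a background rate (0.05);
  all other terms are background everywhere.

What the generator does **not** emulate: read-level sequencing (coverage,
error models), isoform structure, composition biases in decoys, GO-term
hierarchy, or library-size effects. Passing tests therefore demonstrate
correctness of the algorithms under the stated generative assumptions, not
performance on real RNA-seq.

# Numerical conventions and degenerate inputs

* All randomness flows from a single integer seed per generator; identical
  seeds give byte-identical outputs.
* Ties: NJ joins the lexicographically smallest label pair; scans prefer
  smaller starts, then the frame order above; nearest-neighbour and best-hit
  ties resolve by id order; threshold ties resolve to the largest value.
* Empty cases: a grid with no edges anywhere returns the largest threshold
  with an explicit flag; family genes with no edges form singleton modules;
  a transcript shorter than one codon translates to empty frames with a
  warning.
* Undefined values (JC correction at $p \ge 3/4$, $\omega$ at $d_S = 0$,
  fold changes from masked stages) are explicit — errors, `NA`s with flags,
  or counted categories — never silently replaced.

# Validation problem sizes

The shipped validation suites run at desk scale on one CPU: 1,000 random
60-codon pairs for the NG86 oracle; 40 random 5–8-taxon additive trees for
NJ; a 50-sequence set for clustering and 25 pairs of 100-mers for alignment
identity; 10,000 null genes for t-test calibration; 100 random instances for
threshold training; and 50 positives / 200 decoys, 200 mutated queries, and
a 1,000-gene, 40-sample two-module matrix for the end-to-end recovery
checks. These sizes were chosen as the smallest at which the binomial error
of the measured rates is comfortably inside the asserted bounds.

# Known limitations

* The domain scanner has no indel states; a single indel inside a real
  domain shifts the frame window and the hit is lost or truncated.
* Clade assignment uses domain columns only; clades separated mainly by K/C
  domains would blur in real data.
* NG86 is a counting method; it has no transition/transversion or codon
  frequency model (no ML dN/dS is attempted).
* The density-minimising threshold depends on the screened gene set; with
  very few genes the profile can be flat and the tie rule (largest
  threshold) then dominates.
* qRT-PCR error modelling stops at replicate averaging; no amplification
  efficiency estimation is performed.

```{r session}
sessionInfo()
```
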