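---
title: "Models and methods behind regbuildr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind regbuildr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regbuildr)
```

regbuildr builds nucleotide-resolution regulatory annotation from three
kinds of epigenomic evidence: bisulfite conversion counts, transcription
factor binding motifs inside ChIP-seq peaks, and per-cell-type genome
segmentations. This vignette explains the statistical models, the
defaults and why they are what they are, what the synthetic generators
do and do not emulate, and where the design was genuinely open.

## The methylation mixture model

Bisulfite treatment converts unmethylated cytosines; methylated
cytosines resist conversion. At a cytosine covered by $n$ reads of which
$k$ are converted, the converted count is modelled as a three-component
mixture:

$$
P(k \mid n) \;=\; \pi_m \,\mathrm{BB}(k; n, \alpha_m, \beta_m)
          \;+\; \pi_u \,\mathrm{BB}(k; n, \alpha_u, \beta_u)
          \;+\; \frac{\pi_0}{n+1},
$$

where $\mathrm{BB}$ is the beta-binomial (a binomial whose success
probability is integrated over a Beta prior, capturing site-to-site
overdispersion) and the third state is a discrete uniform on
$\{0,\dots,n\}$ for sites whose methylation status is genuinely
undetermined. Because conversion marks *un*methylation, the methylated
component is the one with the **lower** mean converted fraction
$\alpha_m/(\alpha_m+\beta_m)$; this ordering is the model's
identifiability convention and is enforced by a post-hoc component swap
after fitting. The uniform component's pmf is $1/(n+1)$ — the natural
reading of a uniform distribution conditioned on the total read count.

### EM fitting

`em_fit()` maximizes the likelihood by EM. The E-step computes per-site
state responsibilities in log space (log-sum-exp); the M-step sets each
mixing weight to its mean responsibility, and re-estimates each
beta-binomial shape pair by bounded L-BFGS-B over
$(\log\alpha, \log\beta)$ — no closed form exists for weighted
beta-binomial maximum likelihood. Shapes are constrained to
$[10^{-3}, 10^{4}]$; if a component's total responsibility collapses to
zero, its shapes are held and a warning is raised rather than crashing.
Sites are first aggregated by unique $(k, n)$ pair with multiplicity
weights; responsibilities depend only on the counts, so this is exactly
the per-site EM, just faster.

Initialization, when no starting model is given, is deterministic:
method-of-moments Beta fits to the lower and upper terciles of the
conversion fractions, with weights $(0.45, 0.45, 0.10)$. Convergence is
declared when the relative log-likelihood change drops below `tol`
(default $10^{-6}$, at most 500 iterations); the trajectory is
non-decreasing, which the test suite asserts at every iteration. Note
that the three-component model is deliberately richer than some data:
fitted to *single*-component data with free weights, EM will happily
split the component in two, which is the correct maximum-likelihood
behaviour, not a bug; single-component recovery is therefore checked by
starting EM from the degenerate weight vector $(1, 0, 0)$, which EM
preserves.

### Calling and the discard rule

`call_states()` computes the three posterior state probabilities per
site and applies a deliberately literal discard rule: a site is
**discarded** only when *all three* posteriors exceed
$\tau = 10^{-4}$ — that is, kept whenever at least one state can be
ruled out at that level. Kept sites are called by arg-max posterior,
ties broken in the fixed order methylated, unmethylated, undetermined.
This means a kept site can still be ambiguous between two states (e.g.
posteriors $0.50/0.49995/5\times10^{-5}$): the rule discards only
sites where nothing can be excluded, and no additional dominance
criterion is applied. The methylation level $(n-k)/n$ (fraction of
unconverted reads) is reported for every site regardless of status.

## Motif features

### Scoring

JASPAR count matrices are turned into log-odds score matrices in the
standard way, with a background-proportional pseudocount $c$ (default
$10^{-3}$):

$$
p_{ib} = \frac{n_{ib} + c\, b_b N_i}{N_i (1 + c)},
\qquad
s_{ib} = \log_2 \frac{p_{ib}}{b_b},
$$

where $N_i$ is the count total of motif position $i$ and $b$ the
background composition. A window's binding score is the sum of its
per-position log-odds; `scan_sequence()` reports every window at or
above a lenient threshold (default 60% of the maximal attainable
score), on both strands, with minus-strand windows scored on their
reverse complement and reported in forward coordinates. Windows
containing N are skipped rather than scored. The 60% figure is purely a
pre-filter to bound output size — the statistically calibrated gate is
the empirical p-value below — and is exposed as a parameter.

### Empirical null and the 5% filter

Analytic p-values for PWM scores depend on a background model one
rarely trusts; instead the null is built empirically:
`build_empirical_null()` scores $N$ windows (default $10^5$, floor
$10^3$) whose bases are drawn i.i.d. from the background composition.
A match's single-tail (upper) p-value uses the add-one estimator

$$
p = \frac{1 + \#\{\text{null scores} \ge s\}}{N + 1},
$$

which can never be exactly zero and is monotone in $s$.
`filter_matches()` retains matches with $p \le 0.05$. By construction,
on background-like sequence the retained fraction converges to the
cutoff — the calibration property the acceptance suite measures at
100,000 windows. Matches are then restricted to those lying **within**
ChIP-seq peaks (`within_peaks()`): full containment, not mere overlap,
matching the intended semantics of a binding site inside an observed
binding region; a one-argument change relaxes this to overlap via
`associate_matches()`, which implements $\ge 1$-base association.

Per-column information content is $2 + \sum_b p_{ib} \log_2 p_{ib}$
bits, computed from the same pseudocounted probabilities, so a
fully-specific column carries 2 bits and a uniform column 0. The score
ratio displayed for a match is its score divided by the optimal score
(1 for a consensus placement; possibly $\le 0$ for poor matches,
reported as-is).

## The consensus regulatory build

`regulatory_build()` summarizes per-cell-type segmentation states and
experimental peaks into one cell-type-agnostic ("MultiCell") feature
set:

1. **Consolidation.** For each of the four feature-generating labels —
   `tss`, `flank`, `enhancer`, `ctcf` — the union of segments across
   all cell types is merged into candidate features of class
   `promoter_with_tss`, `promoter_flank`, `enhancer`,
   `ctcf_binding_site`. Class overlaps are resolved by the priority
   `tss > flank > enhancer > ctcf`, subtracting higher-priority
   footprints from lower-priority candidates. This makes all features
   pairwise disjoint. The remaining four labels (`transcribed`,
   `repressed`, `low`, `heterochromatin`) never create features.
2. **Unexplained evidence.** Peaks overlapping no feature are merged
   per evidence kind and become `tf_binding_site` or `open_chromatin`
   features (assay names such as DNase or ATAC mark open chromatin).
   Consequently no evidence peak is silently dropped — every peak
   either overlaps a feature or contributed to a new one.
3. **Activity.** A feature is active in cell $c$ iff it overlaps a
   segment of $c$ whose label maps to the feature's own class, or any
   peak observed in $c$. Binary overlap is used rather than a signal
   threshold — the simplest rule consistent with evidence-backed
   activity; unannotated-evidence classes have no generating label, so
   their activity comes from peaks alone. A cell contributing no data
   leaves all features inactive there, with a warning.
4. **Stable ids** are positional (`prefix` + zero-padded rank in
   (contig, start, class) order), so identical input reproduces
   byte-identical GFF3.

One subtlety of the priority scheme: adding a new cell type can
*reassign* bases between classes (a new cell's `tss` segments subtract
bases from another cell's `flank` candidates), so per-class coverage is
not monotone in the number of cells; the top-priority class and the
union of all classes are. We regard this reassignment as correct
behaviour — promoter evidence should outrank flank evidence wherever
both exist — and test the monotonicity that actually holds.

## Variant consequences in motifs

For a single-nucleotide variant inside a motif match,
`motif_consequence()` reports the motif position (strand-aware: on
minus-strand matches positions index from the 3'-most genomic base and
alleles are complemented), whether that column carries at least 1.5
bits of information — the conventional threshold for a "highly
informative position" — and the binding-score change
$s_{i,\mathrm{alt}} - s_{i,\mathrm{ref}}$ in log2-odds units. Because
only one position changes, rescoring the whole window is unnecessary,
but the tests verify the equality against a full window re-scan.
Swapping ref and alt negates the change. Information content uses the
same pseudocounted probabilities as scoring, keeping the two modules
consistent. Non-SNV variants overlapping a match are reported with the
overlap flag but no score change.

## Synthetic data: what it does and does not emulate

The generators exist so every pipeline stage has a self-contained,
seeded test surface; they are pure functions of their parameters and
seed and never perturb the caller's RNG stream.

* `simulate_methylome()` draws hidden states from the mixing weights
  and counts from the state distributions, with coverage
  $n = 1 + \mathrm{Poisson}(15)$ — a realistic WGBS-like mean coverage
  with $n \ge 1$ guaranteed. The default study condition used in the
  acceptance suite is weights $(0.45, 0.45, 0.10)$ with well-separated
  components $\mathrm{BB}(2, 38)$ and $\mathrm{BB}(38, 2)$ (mean
  conversion 5% and 95%), 20,000 sites.
* `simulate_genome()` draws i.i.d. bases; `plant_motifs()` overwrites
  non-overlapping windows with the PWM consensus (planting the
  consensus, rather than sampling from the PWM, makes scan recall
  exactly testable; a sampling mode exists behind a flag);
  `make_peaks()` wraps plants in fixed flanks; `make_segmentation()`
  materializes an explicit per-cell design.

What the generators do **not** emulate: correlated methylation along
the genome, non-uniform genomic base composition and repeats,
chromatin-state spatial structure, read-level artefacts, or
peak-calling noise. Passing tests therefore demonstrate correctness of
the algorithms under their stated models, not performance on real
tissue data; on real data the empirical null should be built from
actual genomic background rather than the i.i.d. composition used in
simulation.

## Numerical choices and problem sizes

* Beta-binomial pmfs are computed via `lchoose`/`lbeta` in log space;
  posteriors and likelihoods use log-sum-exp throughout.
* EM shape updates are warm-started from the current shapes, so the
  numerical M-step cannot decrease the objective; the monotonicity of
  the trajectory is asserted to $10^{-8}$ per step.
* Empirical p-values use `findInterval` on the sorted null — exact
  tie handling is verified against a direct counting oracle.
* Test and acceptance problem sizes — 20,000 methylation sites,
  100,000-base background, 100,000 null windows — are the package's
  chosen study conditions: large enough that Monte-Carlo error is well
  inside the stated tolerances (binomial s.e. of the 5% retention at
  $10^5$ windows is $\approx 0.07$ points), small enough to run in
  seconds.
* Arg-max ties in calling are broken in a fixed documented order;
  stable ids and all writers are deterministic, making whole-pipeline
  reruns byte-identical.

## Known limitations

* The empirical null models mononucleotide background only;
  dinucleotide or GC-stratified nulls are out of scope.
* Motif p-values are calibrated marginally per PWM; no multiple-testing
  adjustment across PWMs is applied.
* The build's activity flag is binary evidence overlap; graded signal
  strength is not consulted.
* Indels in motifs receive overlap annotation but no score change.
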