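---
title: "Methods: calling cytoplasmic polyadenylation targets from RIP-seq"
author: "cpeTargets authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling cytoplasmic polyadenylation targets from RIP-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpeTargets)
```

## The problem

Cytoplasmic polyadenylation re-extends the shortened poly(A) tail of a
stored mRNA and reactivates its translation. The CPEB protein family drives
this process by binding cytoplasmic polyadenylation elements (CPEs) in
3'-UTRs. Identifying which transcripts a CPEB protein actually controls in a
given cell type takes two orthogonal lines of evidence:

1. **physical binding** — RNA immunoprecipitation sequencing (RIP-seq) of
   the protein, contrasted against the same pull-down after shRNA knockdown
   of the protein, so that transcripts depleted in the knockdown IP are
   called *bound*; and
2. **sequence competence** — a combinatorial scan of the 3'-UTR for CPEs and
   the polyadenylation hexanucleotide (HEX), whose number, spacing and
   overlap determine whether a transcript can be activated (or is held
   repressed) by cytoplasmic polyadenylation.

`cpeTargets` implements both stages, plus the two analyses typically used
downstream of them: gene-set enrichment of the bound set against a ranked
expression contrast (is the target set lineage-enriched?), and a two-channel
single-cell immunofluorescence classifier for tissue-level co-expression
validation of a target and its regulator. Every stage has a seeded
synthetic-data generator with planted ground truth, so the full pipeline is
testable end to end without any external data.

## RIP enrichment model

### The count model and its noise structure

Each replicate is a *paired* set of two libraries: a control IP and a
knockdown IP, prepared and sequenced together. For transcript $i$ in sample
$j$ we model fragment counts as

$$x_{ij} \sim \mathrm{Poisson}(s_j\, q_i\, e_{ij}\, G_{ir})$$

where $s_j$ is the library size factor, $q_i$ the transcript abundance,
$e_{ij}$ the planted IP enrichment (the fold change for bound transcripts in
control IPs, 1 otherwise), and $G_{ir} \sim \Gamma(1/\phi, 1/\phi)$ is a
transcript-specific immunoprecipitation-efficiency factor of replicate $r$.
Marginally each count is negative binomial with mean $\mu = s_j q_i e_{ij}$
and variance $\mu + \phi\mu^2$ — standard RNA-seq-like overdispersion, with
$\phi = 0.1$ as the default.

The crucial modelling decision is that $G_{ir}$ is **shared by the two
libraries of a pair**. Crosslinking efficiency, epitope accessibility and
pull-down recovery of a given transcript vary substantially between
experiments, but the paired IP libraries of one replicate are subject to
that variation *together*. Under this structure, conditioning on the pair
total $t = x_{\mathrm{ctrl}} + x_{\mathrm{sh}}$ cancels $q_i G_{ir}$
exactly, and

$$x_{\mathrm{ctrl}} \mid t \;\sim\; \mathrm{Binomial}\!\left(t,\;
  \frac{s_{\mathrm{ctrl}}}{s_{\mathrm{ctrl}} + s_{\mathrm{sh}}}\right)$$

under the null of no enrichment. The exact conditional binomial test
(`testEnrichment()`) is therefore exactly calibrated — in fact conservative,
because of the discreteness of the binomial tail — regardless of how large
$\phi$ is.

This robustness does **not** extend to overdispersion that is independent
between the two libraries of a pair. If each library drew its own $G$, the
conditional distribution of $x_{\mathrm{ctrl}}$ given $t$ would be
beta-binomial-like, with a variance inflated by roughly $1 + \phi\mu$, and
the binomial test would be strongly anti-conservative. It is worth being
explicit about what happens in that regime: with a single pair per
replicate, a four-fold change at $\phi = 0.1$ sits near the information
limit of *any* calibrated per-pair test (the maximal expected $z$ is about
$\log(4)/\sqrt{2\phi} \approx 2.8$ per replicate), so no choice of test
recovers such targets reliably while controlling the FDR. For that regime
the package ships a fixed-dispersion negative-binomial likelihood-ratio
variant (`testEnrichmentNB()`), which stays calibrated at the cost of the
power the binomial test only appears to have. The paired-efficiency model is
both the more realistic description of a paired pull-down design and the
regime in which the pipeline's sensitivity/FDR guarantees hold; the
simulator implements it, and the calibration tests in the package verify
both claims (exactness under the shared factor; the type-I level of the
test on null simulations).

### The filter funnel

`callTargets()` applies, per replicate and in this order:

1. **FPKM floor** (default 0.05): transcripts below the floor in *both*
   conditions are excluded before testing.
   $\mathrm{FPKM} = 10^9 x / (\ell\, s)$ with $\ell$ the transcript length.
2. **enrichment test** on the remaining transcripts;
3. **BH adjustment** over the tested (post-floor) set only — the
   denominator set is fixed by this package to the post-floor set, since
   upstream tools differ on this point;
4. **direction filter**: significant means $q < 0.05$ *and* positive log2
   fold change (computed on library-size-normalized counts with a 0.5
   pseudocount, so zero counts give finite values);
5. **biotype filter**: noncoding transcripts never enter the bound set;
6. **replicate intersection**: the final bound set is the intersection of
   per-replicate bound sets. Replicates corroborate; they are never pooled.

The floor's "both conditions" is interpreted within a replicate (the paired
control and knockdown IP), not across replicates.

## The 3'-UTR combinatorial code

### Element catalogue

`defaultCatalogue()` ships six element families. The CPE consensus
UUUUA$_{1-2}$U expands to exactly `UUUUAU` and `UUUUAAU`. The canonical HEX
is `AAUAAA`; its non-consensus family (`HEXNC`) is the set of eleven common
single-substitution hexamer variants led by `AUUAAA`. The AU-rich element
is the `AUUUA` pentamer, and the Pumilio-binding site is `UGUANAUA` with one
degenerate position. Published scans differ in which non-consensus CPE
variants they admit, and no single authoritative list exists; the `CPENC`
defaults here (`UUUUAAAU`, `UUUUCAU`, `UUUUCAAU`) are deliberately
conservative U-rich single-change variants, and the entire catalogue is
overridable from a config file precisely so that a specific published
variant table can be dropped in. Classifications obtained with the default
catalogue should be read as *a* CPE code, not *the* one.

### Scanning semantics

Scanning reports **every** match of every pattern, including overlapping
and self-overlapping matches, as 1-based closed intervals on the UTR
(5'→3'; DNA input is converted T→U). Two rules keep feature counts honest:
a window matching both a consensus and a non-consensus pattern of the same
family is reported once with the consensus kind, and identical
(kind, window) duplicates are collapsed. Ambiguous bases are rejected by
default (the transcript is named in the error) or, under `mask`, simply can
never match. The scanner is validated against a brute-force
every-pattern-at-every-offset oracle, both on random sequences and
exhaustively on short sequences.

### Classification rules

`classifyRegulation()` applies a deterministic rule table to the motif map:

* any CPE (consensus or non-consensus) overlapping a HEX ⟹
  **repression-configured** — the overlap precludes simultaneous occupancy;
* otherwise, ≥1 CPE and ≥1 consensus HEX with the nearest CPE–HEX gap
  within `[dMin, dMax]` nt ⟹ **activation-competent**;
* otherwise **non-regulated**.

Repression takes precedence over activation when both configurations are
present. The distance window defaults to 0–100 nt; since published
descriptions of the code state that CPE–HEX *localization* matters without
fixing a universal threshold, the window is an exposed parameter, not an
assertion. Note a deliberate consequence of the rule table: a UTR with both
elements present but out of window classifies as non-regulated, so
"non-regulated" does not imply the elements are absent. Non-consensus HEX
variants are counted as features but carry no rule weight by default — the
cleavage machinery tolerates them, but their competence for *cytoplasmic*
re-adenylation is less established. ARE and PBS counts are reported as
auxiliary features and do not enter the default rule table.

## Set analysis

The enrichment score is the weighted Kolmogorov–Smirnov running-sum
statistic: walking a ranked gene list, members of the set add
$|t_i|^w / \sum_{\mathrm{hits}} |t|^w$, non-members subtract $1/(N - N_h)$,
and the score is the signed maximum deviation, always in $[-1, 1]$. Weight
$w = 1$ is the default; $w = 0$ gives the classical unweighted statistic
used by the exhaustive oracle tests. Rankings sort by decreasing statistic
with ties broken lexicographically by id, so results are fully
deterministic.

Because the expression matrix behind a published contrast is usually not
available, the permutation null is a **gene-label permutation** (random
same-size sets), not a phenotype permutation:
$p = (1 + \#\{|ES_{null}| \ge |ES|\})/(1 + n_{perm})$ with $n_{perm} = 1000$
by default and a mandatory seed. BH adjustment is applied across the gene
sets of a run, and the `enriched` flag uses the conventional exploratory
cutoff FDR < 0.25. Gene-label nulls are narrower than phenotype nulls (they
ignore inter-gene correlation), which is the main caveat when interpreting
the flag.

Set comparison (`compareTargetSets()`) reports the exact unique fraction
$|A \setminus B| / |A|$. For concordance between two analysis methods,
`methodConcordance()` reports Pearson and Spearman coefficients with
two-sided p-values; its `significant` flag follows a coefficient-threshold
convention (both $r > 0.5$) retained from the protocol this package
mirrors — an unusual rule, which is why the p-values are always reported
alongside.

## Single-cell co-expression

Intensities are on the 8-bit 0–255 scale. A channel signal below 10% of the
maximum — $\lfloor 0.10 \times 255 \rfloor = 25$ — is background; only
cells with *both* channels below threshold are masked entirely (a cell with
one expressed channel is classified, not discarded). Non-background cells
are classed by the red/green ratio: red > 2, green < 0.5, yellow in between
with both boundaries belonging to yellow. A zero green channel with red
signal yields an infinite ratio and class red.

"Co-expressing" is operationalized as both channels at or above threshold.
This is broader than the yellow class (which additionally requires the two
signals to be within two-fold); both quantities are reported so the
distinction stays visible. The Pearson correlation is computed over
non-background intensity pairs.

## Synthetic data: what it emulates, and what it does not

* `simulateRipCounts()` emulates paired two-replicate RIP-seq at
  2,000 transcripts with 50 bound at 4-fold enrichment, dispersion
  $\phi = 0.1$, deliberately unequal library sizes (factors 1.0, 1.3, 0.8,
  1.1 — so offset handling is always exercised), log-normal abundances with
  a median unenriched IP depth of 50 fragments, and 5% noncoding
  transcripts among the unbound. Planted bound transcripts are always
  coding, so recovery measures the statistics, not the biotype filter.
* `simulateUTRs()` plants exact element arrangements — CPE + in-window HEX,
  CPE overlapping HEX (the `UUUUAAUAAA` arrangement), or nothing — into
  backgrounds made pattern-free by rejection sampling *against the active
  catalogue* (not by alphabet restriction, so fixtures stay valid when the
  catalogue is reconfigured). Each assembled sequence is re-checked and
  junction artefacts trigger resampling, so the emitted truth is exact.
  Class proportions are allocated by largest remainder, i.e. exactly.
* `simulateCells()` plants an exact number of dual-expressing cells
  (correlated bivariate log-normal, latent correlation 0.7 — the order of
  marker co-variation reported for dual-stained tumour tissue — clipped to
  the intensity range with both channels at or above threshold) and splits
  the remainder between single-channel and background populations.

All generators are pure functions of their seed: identical seeds give
byte-identical outputs. What the generators do **not** emulate: positional
biases and mappability structure of real libraries, UTR base composition
(backgrounds are uniform-random subject to rejection), isoform-level
ambiguity, and segmentation noise upstream of the per-cell intensity
table. A pipeline that recovers planted truth here is therefore shown to be
*correct*, not shown to be *robust to every artefact of real data*.

## Numerical and design choices

* Intervals are IRanges (1-based, closed) throughout; conversion happens
  only at the GFF3 boundary, which is 1-based inclusive by definition.
* Overlap means sharing at least one position; the CPE–HEX distance is the
  gap between closest interval ends (0 for adjacent intervals), taken as
  the minimum over all CPE–HEX pairs.
* log2 fold changes use a 0.5 pseudocount on counts normalized to the mean
  library size of the pair.
* `p = 1` whenever a pair total is zero; floored transcripts carry `NA`
  p-values and never enter the BH denominator.
* BH is delegated to `stats::p.adjust`; the test suite checks it against a
  longhand step-up oracle, and the enrichment-score implementation is
  cross-checked against an independent implementation (fgsea) at weight 1
  and against exhaustive enumeration at weight 0.
* Degenerate inputs fail loudly: empty gene sets, whole-ranking gene sets,
  zero-variance correlation inputs, all-background cell tables, replicates
  missing a condition, and duplicate transcript ids are all errors naming
  the offending object.

## Problem sizes used in the checks

The packaged checks run the pipeline at the study-scale defaults: 2,000
transcripts (50 bound), two replicates; 100 planted UTRs; 5,000 cells;
10,000 random sequences against the scan oracle plus an exhaustive sweep of
all two-letter-alphabet sequences up to length 10; 200 random gene sets
with 199 permutations each for the GSEA null; 2,000 null transcripts for
the count-test level. These sizes keep every Monte-Carlo standard error
small relative to the tolerance it is compared against.

## Known limitations

* The exact CPE/HEX variant repertoire and the activation/repression
  distance thresholds are field parameters, not constants; results depend
  on the catalogue and window configured.
* With one IP pair per condition and replicate, the enrichment test leans
  on the paired-efficiency assumption discussed above; designs whose paired
  libraries do not share pull-down variation should use the NB variant and
  expect substantially lower power.
* The gene-permutation GSEA null understates inter-gene correlation.
* The co-expression classifier starts from per-cell intensities;
  segmentation quality is upstream of, and invisible to, this package.
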