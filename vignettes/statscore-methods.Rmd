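---
title: "STAT scores from cytokine-stimulation RNA-seq: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{STAT scores from cytokine-stimulation RNA-seq: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(STATscore)
```

## The problem

Engineered cytokine receptors on T cells are expected to reproduce the
transcriptional program of a native cytokine, often at attenuated strength
(partial agonism). To quantify *which* STAT program a condition engages and
*how strongly*, STATscore implements a signature-scoring procedure for bulk
RNA-seq of a stimulation panel: one unstimulated control condition (an
orthogonal receptor without intracellular signalling domain, here `noICD`),
six reference cytokine conditions (IFN&alpha;, IL-10, IL-21, IL-2, IL-7,
IL-4), and any number of query (chimera) conditions, with three replicates
each.

The procedure has four stages:

1. **Differential expression.** Each reference cytokine condition is
   contrasted against the control with a negative-binomial Wald test; genes
   with BH-adjusted *p* < 0.05 are "driven" by that cytokine, in either
   direction (induced or repressed).
2. **Signature algebra.** Cytokines map to STATs: IFN&alpha;-driven genes
   are the STAT1-driven set and IL-4-driven genes the STAT6-driven set;
   STAT3-driven genes are the intersection of the IL-10- and IL-21-driven
   sets, and STAT5-driven genes the intersection of the IL-2- and
   IL-7-driven sets. Each STAT's *exclusive* set removes every gene driven
   by any other STAT.
3. **Scoring.** Expression is normalized to transcripts per million (TPM).
   A sample's STAT score is the mean Pearson correlation, over the STAT's
   exclusive gene set, between the sample's profile and each reference
   sample of that STAT (a reference sample is excluded from its own panel).
4. **Summaries.** Condition means, fold change of condition-mean scores
   versus the control condition, and PCA of the sample-by-STAT score
   matrix.

## The differential-expression model

For a gene with normalized group means $\mu_1$ (control) and $\mu_2$
(treated), dispersion $\phi$ and group sizes $n_1, n_2$:

$$\log_2\mathrm{FC} = \log_2\frac{\mu_2 + c}{\mu_1 + c},\qquad
\mathrm{Var}(\ln\hat\mu_i) \approx \frac{1}{n_i}
\left(\frac{1}{\hat\mu_i} + \phi\right),$$

with the Wald statistic $\log_2\mathrm{FC}/\mathrm{se}$ referred to a
standard normal, two-sided. Size factors are median-of-ratios (median over
all-positive genes of count over per-gene geometric mean; total-count
scaling normalized to geometric mean one is the fallback when no gene is
positive everywhere). Dispersion is estimated per gene by method of moments
from the pooled within-group variance, floored at $10^{-4}$.

This is a deliberately simple NB test: no dispersion shrinkage across
genes, no fold-change shrinkage, no independent filtering, no outlier
replacement. At three replicates per group the per-gene moment estimator is
noisy, which makes the realized false-discovery proportion of a single
contrast exceed the nominal FDR (the package's own simulations show
realized FDR near 25-30% for single-cytokine contrasts at $n=3$). Two
design features absorb this: intersections (STAT3, STAT5) keep only genes
discovered independently in two contrasts, and the exclusivity subtraction
removes genes that recur across STATs. At twenty replicates per group the
test is well calibrated (type-I error at nominal 0.05 within [0.035,
0.065]; Kolmogorov-Smirnov distance of null p-values to uniform below
0.05), which the test suite verifies.

Tunable parameters: `alpha` (FDR threshold, default 0.05), `pseudocount`
($c$, default 0.5 normalized counts; 0 gives exact fold changes on
positive fixtures), `dispersionFloor` ($10^{-4}$), and an optional
minimum-total-count filter (off by default).

## Signature algebra choices

Two points are genuinely open in this procedure and are resolved as
explicit, configurable defaults:

* **Sign concordance in intersections.** A gene induced by IL-10 but
  repressed by IL-21 cannot represent a shared STAT3 program, so
  sign-discordant genes are dropped from intersections (logged); an
  id-only mode keeps them.
* **Exclusivity against driven sets.** The exclusive set subtracts other
  STATs' *driven* sets (not their exclusive sets), the literal reading of
  "driven by the STAT of interest but not driven by other STATs".

Exclusive sets smaller than `minSize` (default 10) are flagged and their
scores reported missing with a reason code: a Pearson correlation over a
handful of genes is dominated by single-gene noise.

## Scoring choices

Scores are computed on $\log_2(\mathrm{TPM}+1)$ by default. The raw-TPM
option exists (`logTPM = FALSE`), but raw TPM across a realistic dynamic
range (baselines spanning several orders of magnitude) concentrates the
product-moment correlation on the few most abundant genes of the exclusive
set: in the package's simulations the effective number of contributing
genes collapses, scores saturate near 0.9 regardless of activation
strength, and the attenuation ordering of partial agonists is resolved
unreliably. The log transform weights genes more evenly; with it, the
condition-mean score of a chimera grid at activations
$\{0, 0.25, 0.5, 0.75, 1\}$ is strictly increasing in every simulation
seed examined. Control-condition scores remain strongly positive under the
log transform, so score fold changes stay well defined.

Other scoring policies:

* **Self-exclusion**: a reference sample is never correlated with itself;
  otherwise reference-condition scores are biased upward by an exact 1.
* **Degenerate pairs**: zero-variance reference columns are dropped, not
  scored 0.
* **Fold-change guard**: fold change is mean score over control mean score
  only when the control mean exceeds `epsilon` (default 0.05); a ratio of
  correlations explodes near zero. The difference (condition minus
  control) is always emitted alongside.
* **Condition means** are unweighted arithmetic means over replicates.
* **PCA** uses the four STAT columns unscaled (scores already share the
  $[-1, 1]$ scale), column-centered, via singular value decomposition;
  component signs are fixed by making each loading's largest-magnitude
  entry positive. A z-scoring option exists but is off by default.

## The simulator

`simulateExperiment()` generates the stimulation design with known truth.
Counts are negative binomial with variance $\mu + \phi\mu^2$ around

$$\mu_{gs} = b_g \cdot 2^{\sum_k s_{gk}\,\alpha_{ck}\,\beta\,[g \in P_k]}
\cdot d_s,$$

where $b_g$ is a log2-normal baseline (log2 mean 6, sd 2 — a typical bulk
RNA-seq dynamic range), $P_k$ the STAT-$k$ program with per-gene signs
$s_{gk}$, $\alpha_{ck}\in[0,1]$ the activation of STAT $k$ in condition
$c$ (partial agonism is an attenuated $\alpha$), $\beta$ the full log2
effect (default 2), and $d_s$ a per-sample depth factor uniform on
$[0.7, 1.3]$.

Defaults define the emulated study: 2,000 genes; four disjoint 200-gene
programs; 30% of program genes repressed (cytokine responses are
predominantly inductive, with a substantial repressed arm); dispersion
$\phi = 0.1$; three replicates; gene lengths uniform on $[500, 10000]$
bases; and five chimera conditions activating STAT3 at
$\alpha \in \{0, 0.25, 0.5, 0.75, 1\}$. Each paired reference cytokine
(IL-10, IL-21, IL-2, IL-7) additionally induces a private off-target
program of 10% of its STAT program's size, so the intersection step has
real work to do — single-cytokine DE sets differ, as they must in any
experiment where intersections are informative. Program overlap is 0 by
default with a configurable `overlapFraction` to exercise the exclusivity
filtering under shared genes.

What the simulator does *not* emulate: read-level structure (no FASTQ, no
alignment), isoforms, batch effects beyond depth, correlated gene-gene
noise, and library-preparation biases. Passing tests therefore demonstrate
the correctness and internal consistency of the procedure under a clean NB
generative model, not its behavior on any particular real dataset.

## Numerical and reproducibility notes

* All randomness flows through a single integer seed; identical
  configuration and seed give byte-identical outputs, which the run
  manifest (md5 per emitted file) makes checkable after the fact.
* TPM columns sum to $10^6$ to machine precision; an all-zero sample is an
  error, not a silent NaN.
* BH adjustment delegates to the standard step-up implementation and is
  tested against an independent quadratic-time oracle; PCA is tested
  against a covariance-eigendecomposition oracle.
* Problem sizes used by the test suite (2,000 genes, up to 40 samples for
  calibration, 100-500 replicates for moment checks) were chosen so that
  Monte-Carlo bands at 3 standard errors are decisive while the whole
  suite stays fast enough to run routinely.

## Worked example

```{r example, eval = FALSE}
cfg <- pipelineConfig(
  simConfig = system.file("extdata", "default_config.txt",
                          package = "STATscore"),
  outDir = "statscore_run", seed = 1)
runPipeline(cfg)
pipelineReport("statscore_run")
```

The run directory contains the simulated inputs (`counts.tsv`,
`lengths.tsv`, `samples.tsv`, `truth.json`), one DE table per reference
condition, per-STAT signature tables with a summary, per-sample scores
with reason codes, condition means with fold changes and differences, PCA
coordinates and variance fractions, a plain-text report, and the manifest.

## Limitations

* The DE stage is not a DESeq2 replacement; with $n = 3$ its realized FDR
  exceeds the nominal level and its driven sets are correspondingly
  noisier than a shrinkage-based analysis would give.
* Scores compare profiles to reference *samples*, so reference quality
  bounds score quality; a contaminated reference panel shifts all scores.
* STAT4 (and any STAT without a reference cytokine in the design) has no
  signature by construction.
* Fold changes of correlations are interpretable only when the control
  score is meaningfully positive; the epsilon guard makes the failure mode
  explicit rather than preventing it.
```
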