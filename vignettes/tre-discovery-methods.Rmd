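---
title: "Methods: in-silico thyroid response element discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in-silico thyroid response element discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trescan)
```

# Overview

`trescan` screens mammalian promoters for thyroid hormone response
elements (TREs): composite binding sites for thyroid hormone receptor
dimers built from two hexameric half-sites related to the consensus
`AGGTCA`. The pipeline has three stages — an expression-based candidate
filter, a PWM motif scan, and a cross-species conservation filter — plus
a synthetic-data generator used for validation. This vignette documents
the model, every tunable parameter with its default and rationale, the
numerical conventions, and the known limitations.

# The half-site PWM

## Model

Given $n$ training hexamers with base counts $c_{i,b}$ at position
$i \in 1..6$, the weight matrix in bits is

$$w_{i,b} = \log_2 \frac{(c_{i,b} + \epsilon)/(n + 4\epsilon)}{q_b},$$

with pseudocount $\epsilon$ and background distribution $q$. A hexamer
scores $\sum_i w_{i, x_i}$. Two anchor facts pin the calculus down: a
perfect consensus against a matrix trained only on that consensus (with
$\epsilon = 0$, uniform background) scores exactly
$6 \times \log_2 4 = 12$ bits, and a fully degenerate matrix (equal
counts everywhere) scores 0 bits for every query.

`build_pwm()` is the fitting function; it returns an S3 object of class
`halfsite_pwm` with `print`, `summary`, `coef`, `predict` (scores new
hexamers), `simulate` (draws hexamers from the implied per-position
distribution) and `plot` (per-position information profile) methods.

```{r}
pwm <- build_pwm(default_training_set())
summary(pwm)
```

## Parameters

* **`pseudocount = 0.25`** — a light Laplace-style smoothing that keeps
  unseen bases finite without washing out strong positions. With 14
  training hexamers, an unobserved base scores
  $\log_2(0.25/15 \cdot 4) \approx -3.9$ bits, a firm but finite
  penalty. Setting `pseudocount = 0` is supported; unseen bases then
  score `-Inf`, a deliberate sentinel meaning "impossible under the
  model", which propagates correctly through sums and threshold
  comparisons.
* **`background`** — uniform by default; promoters are GC-skewed in
  places, but the scan thresholds were chosen against the uniform
  background, so the two must be changed together.
* **Training set** — the packaged `default_training_set()` is a
  14-hexamer curated stand-in assembled from canonical receptor
  half-site variants (`AGGTCA` and single-step neighbours). It exists so
  that the package is self-contained and its defaults well-behaved: the
  consensus scores ≈ 10.08 bits and common natural variants score above
  the high threshold. For a real screen, supply your own validated
  half-sites via `read_training_tsv()`; `leave_one_out_scores()` helps
  audit a candidate set.

# Motif scan

## Architectures and geometry

Three dimer architectures are scanned, each defined by its spacer and
the orientation of its half-sites:

| name | arrangement     | spacer | element length | half-site extraction |
|------|-----------------|--------|----------------|----------------------|
| DR4  | direct repeat   | 4      | 16             | first 6, last 6 |
| IR0  | inverted repeat | 0      | 12             | first 6, revcomp(last 6) |
| ER6  | everted repeat  | 6      | 18             | revcomp(first 6), last 6 |

The extraction geometry is what makes, e.g., the everted element
`TGACCTTTATGCAAGTCA` decompose into the half-sites `AGGTCA` (reverse
complement of `TGACCT`) and `AAGTCA`.

## Hit rule and thresholds

A window is a hit when `min(bits1, bits2) >= low_bits` and
`max(bits1, bits2) >= high_bits` — i.e. one strong and one at least
moderate half-site, in either order. Defaults:

* **`low_bits = 3.76`** — the classical "half the maximum information
  above background for a reasonably specific site" operating point for
  hexamer half-sites; permissive enough to admit one degenerate
  half-site per element.
* **`high_bits = 6.0`** — half of the 12-bit maximum; requires the
  anchor half-site to be close to consensus.

Both are plain parameters of `scan_thresholds()`; every scan function
takes a `scan_config`, and tests exercise randomized thresholds, so
nothing in the package depends on these exact values.

## Numerical and coordinate conventions

* Promoter windows are TSS-anchored, default −8000..+2000. A hit's
  `pos` is the TSS-relative coordinate of the element's **5′-most
  base** (TSS = 0, negative upstream): `pos = window_start + offset0`
  where `offset0` is the 0-based offset in the window.
* Windows containing `N` are handled by skipping every element window
  that overlaps an `N` (implemented with a cumulative-count trick, so
  the scan stays vectorized); an element is never scored on ambiguous
  sequence.
* The scan is **sense-strand by default**. TRE half-site arrangements
  are partially strand-symmetric (an IR0 is its own reverse complement
  up to half-site identity), so scanning both strands double-reports
  palindromic hits; `scan_config(both_strands = TRUE)` enables the
  reverse strand for asymmetric use cases, reporting minus-strand hits
  at the 5′-most plus-strand coordinate of the element.
* The scanner is vectorized: the sequence is integer-encoded once and
  each architecture's two half-site bit tracks are computed with six
  vector lookups each (reverse-complement tracks use the complement
  identity `code_rc = 5 - code`). An exhaustive substring-based
  re-scorer is kept in the test suite as an independent oracle; the two
  agree exactly on hundreds of randomized promoters.

# Conservation filter

Mouse hits are filtered through rat, then human:

1. For each mouse element, slide an ungapped window of the same
   architecture across the ortholog promoter within
   **±`max_distance_bp` (default 2000, inclusive at exactly 2000)** of
   the mouse position.
2. Count **half-site mismatches only** (the spacer is free to drift; it
   carries no direct receptor contact). Keep candidates with
   `max_mismatches <= 2` per ortholog.
3. Require the better of the ortholog's two extracted half-sites to
   score at least **`min_pwm_bits` (default 3.76)** — a guard against
   "conserved" matches that are no longer plausible binding sites.
4. Rank surviving candidates by a substitution score — match +1,
   mismatch 0, and −1 when a mouse **G at half-site positions 2 or 3**
   (the most information-rich, receptor-contacting positions) is
   mismatched. The score is used for ranking only, never for
   acceptance; ties are all retained.

An element survives the funnel if it has at least one accepted rat
match and at least one accepted human match; the output table contains
one row per (element × rat match × human match) combination so that no
ranking decision is hidden. Genes without an ortholog promoter are
skipped with a message and recorded in the funnel report rather than
silently dropped.

# Expression filter

Genes are classified from per-sex fold-change/FDR records across three
comparisons — hypothyroid (`hypo`), hyperthyroid (`hyper`), and
hypothyroid-plus-T3 (`hypo_plus`), each vs control. A sex shows the
direct-regulation pattern when:

(a) at least one of `hyper`/`hypo_plus` is significant
    (`fdr_p < alpha`, default 0.05);
(b) significant `hyper` and `hypo_plus` agree in sign;
(c) a significant `hypo` is **not** in the same direction as a
    significant `hyper`/`hypo_plus` (hormone removal and hormone excess
    should move a direct target in opposite directions);
(d) significant `hypo` and `hypo_plus` do not share a sign.

A gene is called **direct** when at least one sex shows the pattern and
no sex contradicts rules (c)/(d). Absent cells are treated as
not-significant. The packaged table of 28 published direct targets
classifies 28/28 direct under these rules.

# Synthetic data generator

`generate_promoter_triplets()` plants one known element per gene in a
random mouse promoter, then derives rat and human promoters by mutating
it; `generate_expression_table()` emits matching expression records with
a truth ledger. Design points:

* **Coupled randomness.** Ortholog substitutions are generated by
  drawing *unconditional* uniforms and thresholding them against the
  substitution rate (common random numbers). Raising the rate can only
  convert non-substitutions into substitutions, never the reverse, so
  planted-element recovery is **deterministically monotone** in the
  rate at a fixed seed — the property the acceptance checks rely on,
  with no Monte-Carlo slack needed.
* Mouse is the unmutated reference; rat and human are independently
  mutated and their element positions jittered by up to
  **`jitter_bp` (default 500)**, comfortably inside the ±2 kb
  conservation band.
* Defaults: `n_genes = 30`, window −8000..+2000,
  `substitution_rate = 0.1` per half-site base (expected ≈ 1.2
  substitutions per ortholog element, mimicking mouse–rat promoter
  divergence), `spacer_mutation_rate = 0.1`, equal DR4/IR0/ER6 mix, a
  4-hexamer half-site pool that all score above the high threshold,
  equal quarters of direct-up / direct-down / indirect / unresponsive
  genes (allocated by largest remainder, so counts are exact, then
  shuffled), `fc_range = c(1.2, 2.0)` for significant fold changes.
  `seed` is **required** — there is no silent global-RNG dependence,
  and the generator never perturbs the caller's `.Random.seed`.
* Every planted fact (position, element, per-base substitutions,
  expression class) is recorded in a truth ledger; a test reconstructs
  each ortholog element from the ledger's substitution strings and
  re-locates every element in the emitted sequence.
* **Realism limits:** promoter background is i.i.d. uniform (no GC
  skew, no repeats), exactly one element per gene, substitutions are
  independent per base (no transition/transversion bias), and ortholog
  divergence contains no indels — consistent with the ungapped
  alignment model, but a simplification of real promoter evolution.

Problem sizes used in the package's own validation (e.g. 25–400 genes,
200 randomized promoters for the scanner oracle, rates 0–0.25) were
chosen to keep the full suite under a minute while leaving binomial
tolerances tight; they are package choices, not external constraints.

# Other decisions

* Published element tables use "Pos." as the 5′-most base of the
  element; the packaged comparison table carries a
  `hamming_consistent` flag because exactly one published ortholog row
  reflects a shifted alignment that plain half-site Hamming distance
  does not reproduce. Tests assert the metric on the consistent rows
  and assert that exactly one inconsistent row exists.
* File formats are plain text: TSV with a leading `#` comment declaring
  the coordinate convention, 6-column BED (0-based half-open offsets
  within the promoter window), JSON via `jsonlite` for the funnel
  report, truth ledger and run manifest. The manifest contains the
  configuration echo and package version but deliberately **no
  timestamp**, so runs are byte-reproducible.
* FASTA I/O goes through `Biostrings`; everything algorithmic (PWM,
  scanner, aligner, classifier, generator) is hand-written base R,
  because those primitives are the package's contribution.

# Limitations

* Ungapped conservation: a single indel near an element in rat/human
  hides a genuinely conserved site.
* No modelling of half-site/spacer interdependence or receptor
  cooperativity; the two half-sites are scored independently.
* The default training set is a curated stand-in, not an experimentally
  validated collection; absolute bit scores shift with the training
  set, so thresholds should be re-examined when substituting one.
* Sense-strand default means anti-sense DR4/ER6 elements require
  `both_strands = TRUE`.
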