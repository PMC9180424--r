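---
title: "Methods: composite haze-tolerance indices from social-media signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite haze-tolerance indices from social-media signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hazetol)
```

## The problem

Haze episodes — winter PM2.5 spikes in heavily industrialised regions —
have a measurable psychological footprint: people post more when the air
is bad, and what they post turns more negative. *Psychological tolerance*
is the capacity to absorb that stress. `hazetol` quantifies it at two
spatial scales from three ingredients: a microblog corpus, a daily PM2.5
series, and an 18-indicator ecological / socio-economic / social-media
panel.

This vignette documents the models, the tunable parameters, the numerical
conventions, and the places where the method leaves genuine design choices
open — and which choices this package made.

## Sentiment model

Sentiment is scored with a two-class multinomial naive Bayes. For a
document with tokens $w_1,\dots,w_k$,

$$P(c \mid d) \propto P(c) \prod_{i=1}^k P(w_i \mid c),
\qquad
P(w \mid c) = \frac{n_{wc} + \alpha}{n_c + \alpha V},$$

with class priors $P(c)$ the training document frequencies, $n_{wc}$ the
token count of $w$ in class $c$, $n_c$ the class's total token count, $V$
the vocabulary size, and $\alpha > 0$ the additive smoothing pseudo-count
(default 1, the standard Laplace choice; $\alpha = 0$ is rejected because
a single unseen word would zero the likelihood). Tokens outside the
training vocabulary contribute the zero-count smoothed mass
$\alpha / (n_c + \alpha V)$. Likelihoods are accumulated in the log
domain; the returned score is the positive-class posterior in $[0,1]$.

**Polarity convention.** A post is positive when its score strictly
exceeds 0.5. A score of exactly 0.5 is classed negative: only scores
*exceeding* the threshold express positive sentiment. This matters for
the aggregates below, where every post must fall in exactly one group.

Documents are represented as token counts (multinomial), not binary
presence, matching the $P(w \mid c)$ formulation. The tokenizer is an
injected dependency: the default lower-cases and splits on whitespace and
punctuation, and a dictionary-based segmenter for unsegmented languages
can be plugged in without touching any downstream contract.

## Keywords, the co-word topic index, and the perception index

TF-IDF uses $\mathrm{tf} = \text{count}/\text{doc length}$ and
$\mathrm{idf} = \ln(N/\mathrm{df})$ with no additive offsets — the
simplest dialect, under which a term present in every document has weight
exactly 0. Ranking ties are broken lexicographically so output is
deterministic.

The **topic index** summarises how central a set of seed terms (e.g.
*haze*, *smog*) is to the discussion. The method's description names a
"co-word network" but no statistic, so the package implements a
documented proxy: build the document co-occurrence network (edge weight =
number of documents where both tokens occur; repeated tokens within a
document count once), sum the weights of edges incident to a seed term,
and divide by the number of documents. The per-document normalisation
makes the index invariant under corpus duplication, and counting
co-occurrence at document granularity makes it invariant to token order.

The **haze perception index** is likewise a formalisation of a verbally
specified quantity: an equal-weighted (by default) sum of three min–max
standardized components — haze-post share, haze-post count, and the topic
index — across the regions of one dataset. Distinct user counts are not
available in the record schema and are omitted. Both proxies are
conventions of this package, not published formulas; treat cross-study
comparisons of their absolute values accordingly.

## AHP–entropy weighting

The provincial evaluation system has three rule layers — ecological
environment (5 indicators), social economy (8), social media (5) — and
ships with four expert pairwise-comparison matrices (one first-level,
three within-layer) as plain-CSV fixtures.

**Subjective weights.** Each judgment matrix is validated (square,
positive, unit diagonal, reciprocal within $10^{-3}$ relative — the
printed matrices are rounded to five decimals) and its priority weights
are the principal eigenvector, computed by power iteration with relative
tolerance $10^{-12}$ and a 10,000-iteration cap; $\lambda_{\max}$ is the
converged Rayleigh quotient. The consistency index is
$CI = (\lambda_{\max} - n)/(n - 1)$ and $CR = CI/RI(n)$ with the
tabulated random-consistency constants $RI(1..9) =$ 0, 0, 0.58, 0.90,
1.12, 1.24, 1.32, 1.41, 1.45; $CR < 0.1$ passes, and $CR \equiv 0$ when
$RI = 0$ ($n \le 2$). All four shipped matrices pass (maximum
$CR \approx 0.087$). Absolute indicator weights are rule-layer weight
times within-layer weight.

**Objective weights.** Indicators are range-standardized across the
evaluation objects: benefit direction $(x-\min)/(\max-\min)$, cost
direction $(\max-x)/(\max-\min)$, with exact zeros then replaced by 0.01
so every share is positive. Entropy weighting follows
$P_{ij} = Y_{ij}/\sum_i Y_{ij}$,
$e_j = -\tfrac{1}{\ln m}\sum_i P_{ij}\ln P_{ij}$ ($m$ = number of
objects, so $e_j \in [0,1]$ exactly), and
$S_j = (1-e_j)/\sum_j(1-e_j)$. A constant column is set to 1 for every
object rather than erroring: it carries no discriminating information,
gets entropy 1 and weight 0, which is the method's intent.

**Combination.** The combined weight is the normalized geometric mean
$\omega_i = \sqrt{\omega_{1i}\omega_{2i}} / \sum_k
\sqrt{\omega_{1k}\omega_{2k}}$ — the closed form that keeps the result
close to both inputs. The composite score per object is
$z_i = \sum_j \omega_j x_{ij} \in [0,1]$, with per-indicator
contributions retained.

**Known irreproducibilities in the published weight table.** The
published absolute-AHP column sums to ≈ 1.024 rather than 1, and its
socio-economic block cannot be derived from the corresponding shipped
matrix under any renormalisation (its entries deviate several-fold from
the eigenvector — most plausibly a row-misalignment in the published
table). The ecological and social-media blocks *do* match the shipped
matrices' eigenvectors within 5% relative once renormalised within-block
(in their source matrices' row order). The published combination-weight
column is also not the normalized geometric mean of its own AHP and
entropy columns. The package therefore asserts agreement only where the
printed inputs support it, and documents the rest here rather than
reverse-engineering it.

**Direction map.** Which of the 18 indicators are cost-type is not
published; it is a required configuration. The packaged default
(`default_directions()`) treats PM2.5 level, pollution days, population
density, secondary-industry share, haze-post volume and the
volume-pollution correlation as costs and everything else as benefits —
a defensible convention, stated once and used consistently.

## The tolerance index and class binning

$$T = \frac{W_{Ep} \cdot A_{Ep}}{W_{EN} \cdot (1 - A_{EN}) \cdot C_{PM2.5}}$$

$T$ scales linearly in the positive-post count and inversely in PM2.5
($T(c \cdot C_{PM2.5}) = T/c$), and increases in both sentiment means —
note $1 - A_{EN}$ measures the *depth* of negativity, so milder negative
posts (larger $A_{EN}$) raise tolerance.

When a polarity group is empty ($W_{Ep}=0$ or $W_{EN}=0$) or
$A_{EN}=1$, $T$ is a **flagged missing value**, never an
epsilon-patched number: a silent epsilon would place the region
arbitrarily within the class bins. Non-positive PM2.5 is an input error.

Defined $T$ values are reclassified into 5 equal-interval classes over
the pooled panel (all periods together), so class codes are comparable
across time — a prerequisite for trajectory coding. Bins are right-open
with the last bin closed at the maximum; with a single defined value the
degenerate range puts it in the top class by convention.

## Trajectory coding and change types

A unit's class states $P_1,\dots,P_q$ over $q > 1$ winters are encoded
positionally, $C = \sum_i P_i\,10^{q-i}$, stored as digit strings (exact
for any $q$; parseable as integers for $q \le 18$). Decoding splits the
digits back; a zero digit is invalid since classes start at 1.

The change type is computed from successive differences: drop zeros
(plateaus inside a shape should not break it — "no change" is the only
flat type), collapse runs of equal sign, then map $() \to$ *no change*,
$(-,+) \to$ *decline–rise*, $(-,+,-) \to$ *decline–rise–decline*,
$(+,-,+) \to$ *rise–decline–rise*, and everything else to *complex*. The
taxonomy has no monotone class, so purely rising or falling sequences are
deliberately assigned to *complex* rather than inventing a sixth type.
The label depends only on state ordering, so any strictly increasing
relabeling preserves it. Units with a missing state are excluded from
coding and listed separately, never dropped silently. Because "number of
distinct trajectory varieties" is ambiguous between raw codes and
collapsed shapes, the summary reports both counts.

## The synthetic-data generator

The generator exists so every downstream stage is testable without the
original (non-public) microblog and yearbook data. Its defaults encode
the study conditions: 7 regions over the 2013–2019 winters, 90-day
seasons, region-mean PM2.5 of 90, 88, 75, 80, 86, 60 and 67 µg/m³ (the
printed winter concentration levels), a 2,000-document labelled training
corpus and roughly 10,000 scoring posts — a desk-scale stand-in for the
original 28,000-post labelled corpus.

Mechanisms, chosen to match the model families the analysis assumes:

- **PM2.5**: daily values lognormal with $\mu_{\log} = \ln m - \sigma^2/2$
  so the arithmetic mean equals the configured region mean $m$; strictly
  positive and right-skewed like pollution data. Default
  $\sigma = 0.3$, a moderate day-to-day spread (CV ≈ 31%).
- **Post volume**: Poisson per region-day with log-link on standardized
  PM2.5 (default slope 0.3) — the simplest count model with the assumed
  monotone coupling.
- **Sentiment**: each post's latent class is Bernoulli with logit-linear
  dependence on standardized PM2.5 (default slope −0.8 around a baseline
  positive share of 0.55); tokens are drawn from class-conditional
  multinomials over a 200-token vocabulary in which 10% of tokens are
  positive-leaning (8× over-represented in positive posts), 10%
  negative-leaning, and five are neutral haze seed terms. This is
  exactly the naive-Bayes generative family, so classifier recovery is
  well-posed.
- **Indicator panel**: the five ecological columns derive from the PM2.5
  series (seasonal mean; days above 75 µg/m³) plus synthetic winter
  weather; the five social-media columns are computed *through the
  package's own sentiment and indicator modules*; the eight
  socio-economic columns are drawn from plausible positive ranges with
  persistent region effects. Their distributional forms are generator
  conventions — the yearbook quantities have no published distributions —
  chosen once as what winter city statistics plausibly look like
  (e.g. population density lognormal around 500 person/km², gender ratio
  normal around 105).
- **Class raster**: per-unit first-order Markov chains over states 1–5
  with a persistence parameter (default 0.6 across 66 units, the study
  area's city count).

All randomness flows from a single integer seed through fixed per-stage
substreams, so identical configurations give byte-identical bundles and
identical output-file hashes in the pipeline manifest.

**What passing tests do and do not show.** The generator reproduces the
*statistical couplings* the method assumes — not real microblog language
(tokens are synthetic symbols; no dialect, sarcasm, or ads), not
spatial autocorrelation between neighbouring cities, not holiday
calendar effects, and not the measurement quirks of scraped data
(duplicates, bots, platform censoring). A pipeline validated here is
validated for its arithmetic and its statistical recovery behaviour, not
for robustness to those real-data pathologies.

## Problem sizes and runtime choices

The test suite exercises deliberately desk-scale configurations: 1–3
regions, 1–3 winters of 20–120 days, 200–2,000 training documents, and
up to ~10,000 posts where a correlation sign must be detected. The
sign-recovery experiment runs 100 seeded replicates of a one-region,
120-day winter with ≈ 5,000 posts each. Exhaustive trajectory checks
enumerate all $5^7 = 78{,}125$ five-state, seven-winter sequences.
These sizes are the package's own choices: large enough that the
law-of-large-numbers and recovery properties hold with margin, small
enough that the full suite runs in well under a minute.

## Known limitations

- The topic and perception indices are documented proxies (see above);
  their absolute scales are package conventions.
- Tolerance classes depend on the pooled min–max range, so adding a
  period can relabel earlier classes; comparisons should fix the panel
  first.
- The naive-Bayes independence assumption is wrong for real text in the
  usual ways; scores are well-calibrated posteriors only under the
  synthetic generative model.
- No geographic operations: units are labels, not geometries; mapping
  and raster algebra live outside this package.
- Post deduplication and advertisement filtering are out of scope — the
  preprocessing contract covers markup, links, emoji and stop words
  only, because no reproducible rule for the rest is available.
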