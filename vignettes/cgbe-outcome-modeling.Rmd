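---
title: "Modeling C-to-G base-editing outcomes from sequence context"
author: "cgbesmart authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling C-to-G base-editing outcomes from sequence context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgbesmart)
```

# The problem

C-to-G base editors (CGBEs) convert a C•G pair into G•C inside a narrow
window of the protospacer, but their efficiency varies strongly with the
sequence context of the targeted C and with its protospacer position, and
several substrate Cs in one protospacer are often co-edited. Given a guide
library sequenced deeply enough to count edited reads per site, this
package answers three questions:

1. *How efficiently is each C converted?* — quantified from reads, then
   predicted for new sites from sequence alone.
2. *Which contexts does an editor prefer?* — a motif model over the
   nucleotides flanking the targeted C.
3. *Which combinations of edits appear in single reads?* — a joint
   distribution over all edit patterns, not just per-position marginals.

Protospacer positions are numbered 1–20 from the PAM-distal end, the PAM
occupies positions 21–23, and after strand normalization only C is treated
as the substrate nucleotide. The high-efficiency editing window spans
positions 4–7.

# Quantification and training tables

Reads are classified against the reference amplicon: equal-length reads by
direct per-position comparison, length-discordant reads by banded global
alignment with affine gaps (match 2, mismatch −2, open −6, extend −1); a
gap inside positions 1–23 marks the read as an indel. On-target efficiency
is the fraction of reads carrying *exactly* the intended edits (indel reads
stay in the denominator); indel frequency is the fraction of indel reads.

Training tables follow a fixed recipe: indel reads are discarded first;
any replicate with fewer than 100 remaining reads is dropped (strict:
totals of 99 fail, 101 pass); surviving replicates are summed per
genotype; add-one smoothing then places one count on every edited outcome
in the site's outcome space so that no outcome has probability zero. The
enumerated outcome space is all subsets of the site's substrate-C
positions up to order 2 (plus any higher-order pattern actually observed);
order 2 keeps the space small while guaranteeing that every cell of every
adjacent-pair 2×2 table used downstream is strictly positive. Per-position
efficiency labels are smoothed edited counts over the smoothed total, so
the denominator excludes indels — the table is assembled entirely from
non-indel reads.

# The motif model

For a targeted C at positions 4–7, flanking nucleotides at relative
positions −k…−1, +1…+k are one-hot encoded (position-major, A\<C\<G\<T) and a
logistic regression maps them to efficiency in [0, 1]. Because labels are
fractional, the fit maximizes the fractional-response (quasi-binomial)
cross-entropy; it is solved by iteratively reweighted least squares with a
tiny L2 ridge (1e-6) on the weights. The ridge matters twice: it makes the
one-hot design (whose per-position columns sum to the intercept) uniquely
solvable, and it resolves the per-position location indeterminacy toward
the symmetric solution whose per-position weight mean is absorbed into the
intercept. Accordingly, reported logo matrices are mean-centered per
relative position — only contrasts between nucleotides are identified.
The default radius is k = 3, which covers the editor preferences usually
summarized as 3-mers (WCW, TCW, CCN) with room to spare; k is a plain
argument, not a fixed constant.

# The window-ensemble efficiency model

Every nucleotide symbol (A, C, G, T, and a dedicated PAD for positions
beyond the available sequence) is embedded into a learned vector of length
16. For each protospacer position, nine base models — window sizes 7, 9
and 11, three independently initialized replicates each — read the
embedded window centered on that position (flanks and PAM included). Each
base model is a feed-forward network with hidden layers of 256 and 128
rectified-linear units and a single sigmoid output; 30% dropout is applied
to hidden activations during training. The ensemble prediction is the
average of the nine outputs under softmax-normalized learned weights, so
"weighted average" holds literally and the prediction stays in (0, 1).

Training minimizes the mean square error over (site, substrate-C
position) pairs with minibatch Adam (learning rate 1e-3, batch 256, at
most 100 epochs, early stopping after 10 epochs without validation
improvement). Positions without a reference C carry no loss. After every
epoch the pooled Pearson R on the validation sites is recorded, and the
parameters of the best validation epoch are the returned checkpoint. The
embedding table is shared across positions and base models for parameter
economy; each position otherwise has its own ensemble, since the effect
of a context nucleotide depends on where the targeted C sits. All
randomness (initialization, shuffling, dropout) flows from one seed, so a
rerun reproduces the validation curve exactly. Everything is plain
double-precision matrix arithmetic, so no specialized runtime is needed.

Degenerate inputs behave predictably: with constant labels the ensemble
converges to the constant; a site without any protospacer C yields only
missing values.

# The chain model over edit patterns

Editing at position i is Bernoulli with marginal p(Xi = 1) supplied by the
efficiency model (or by observed frequencies). Dependence between
positions is reduced to adjacent substrate-C pairs, summarized by the odds
ratio

c = p11·p00 / (p01·p10),

where p11/p00 are the concordant and p01/p10 the discordant cells. Given
margins (pA, pB) and c, the unique admissible joint has

p11 = (b − sqrt(b² − 4c(c−1)·pA·pB)) / (2(c−1)),  b = 1 + (c−1)(pA+pB),

the root lying strictly inside the Fréchet bounds
max(0, pA+pB−1) \< p11 \< min(pA, pB); c = 1 reduces to independence, and
bisection backs up the closed form when the discriminant is numerically
marginal (tolerance 1e-12). Conditional tables
p(Xi | Xi−1) follow by row normalization, and the joint over all patterns
factorizes forward as p(X1)·p(X2|X1)⋯p(Xn|Xn−1), which reproduces every
input marginal exactly and preserves every adjacent odds ratio. Exact
enumeration covers n ≤ 12 substrate Cs (4096 patterns); longer chains use
ancestral sampling. Marginals at exactly 0 or 1 are clipped to
[1e-9, 1−1e-9] with a warning, and estimated odds ratios are capped to
[1e-4, 1e4] to guard against smoothing artifacts.

## Estimating c across sites

c is estimated from the training table per pair of absolute protospacer
positions, pooled over sites. Collapsing the 2×2 cells across sites
before taking the ratio would attenuate the estimate whenever marginals
differ between sites (the classic aggregation bias of odds ratios: in our
simulations a planted c = 4 collapsed to ≈2.2–3.0), so the package pools
with the Mantel–Haenszel stratified estimator,
c = Σs(n11·n00/N) / Σs(n10·n01/N) over per-site strata — the standard
common-odds-ratio estimator, which reduces to the plain formula for a
single site. Position pairs never observed in training fall back to the
global Mantel–Haenszel estimate over all pairs rather than to
independence, since adjacent co-editing is a property of the editor more
than of the exact position pair.

# The synthetic library generator

The generator emulates a paired guide/target oligonucleotide library:
uniform-random 20-nt protospacers, an NGG PAM at positions 21–23, 10-nt
flanks, and per-C true efficiencies
logistic(baseline + window boost·[position ∈ 4–7] + A/T-neighbor boosts),
i.e. a planted WCW-type motif preference plus the editing-window effect.
Read counts per replicate are negative-binomial around the configured
coverage; indel reads arrive at a configured rate; non-indel reads receive
correlated binary edits across substrate Cs sampled from the same
margins-plus-odds-ratio chain the inference assumes, so the generator is
also the oracle for the proportion model. Read-level simulation
additionally produces bystander C-to-A/T conversions and, for
reverse-orientation sites, reverse-complemented read strings. Each site
draws from a random stream derived from (seed, site id), so results do not
depend on processing order.

Defaults (baseline logit −1, window boost +1, A/T neighbor boosts +0.8,
coverage 1000 with dispersion 10, 5% indels, 2% bystanders, adjacent odds
ratio 4, two replicates) put true efficiencies in roughly 0.27–0.83 — a
spread in which every model stage has signal to recover. What the
generator does *not* emulate: sequencing errors, PCR duplicates,
coverage–context correlations, genomic (non-uniform) flank composition,
and editor-specific indel spectra. Passing the recovery tests therefore
demonstrates correctness of the estimators under the generative
assumptions, not performance on any real library.

# Evaluation protocol

Sites (never individual positions) are split 6:1:3 into train, validation
and test by seeded shuffle with largest-remainder rounding; a 4:1
train/validation preset covers the case where testing happens on external
sites. Trisection cross-validation splits sites into three folds, each
serving once as test with 10% of the training portion held out for
validation, and merges the per-fold test predictions so every site is
predicted exactly once. Metrics are Pearson R and RMSE, either pooled over
all (site, position) pairs or as the unweighted mean of per-position
correlations (positions with undefined variance are skipped and counted).

# Problem sizes and numerical choices

The bundled tests and the acceptance script run the full stack at
moderate scale as the package's own benchmark sizes: 5000 sites (~1000×
coverage) for efficiency-model recovery, 2500 sites in the acceptance
script, 2000 sites for motif recovery, 300 sites at ~5000× coverage for
proportion recovery, and 200 sites at ~2000× for read-level
quantification. At these sizes held-out pooled Pearson R against
generator truth is ≈0.99 for the efficiency ensemble and ≥0.9 for the
motif model inside the editing window, estimated adjacent odds ratios
fall within ±25% of the planted value for (nearly) every pooled position
pair, and held-out outcome-proportion distributions sit within
total-variation distance 0.05 of truth (mean ≈0.02) at the 300-site
scale.

Other numerical choices: IRLS stops at gradient norm ≤ 1e-8; the
bivariate root is accepted only inside the open Fréchet interval;
enumeration asserts Σ patterns = 1 ± 1e-9; ties in largest-remainder
rounding resolve by fraction order. Known limitations: only C-to-G
substitutions define the modeled outcome space (A/T bystander calls are
tracked at read level but fold into the unedited class of the pattern
space — the binary "edited" indicator means edited-to-G); dependence
beyond adjacent substrate pairs is not modeled; the read classifier is a
deterministic stand-in, not a full realignment pipeline; and per-position
ensembles mean positions rarely holding a C in training are predicted
from few examples.
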