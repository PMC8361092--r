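# cgbesmart

Modeling and prediction of C-to-G base-editing outcomes from sequence
context.

C-to-G base editors (CGBEs) install C•G → G•C transversions within a
narrow window of the protospacer (positions 4–7, numbering 1–20 from the
PAM-distal end, PAM at 21–23). Their efficiency depends strongly on the
nucleotides flanking the targeted C (WCW-type motif preferences), and
several substrate Cs in one protospacer are co-edited in correlated
fashion. This package is for researchers who sequence guide/target
libraries or endogenous amplicons and want to (a) quantify editing
outcomes from reads, (b) learn an editor's context preferences, and
(c) predict both per-position efficiencies and the full distribution of
edit patterns at new target sites.

## What is inside

- **Quantification** (`classifyReads`, `onTargetEfficiency`,
  `indelFrequency`, `assembleTrainingTable`): read classification against
  the reference amplicon; on-target efficiency = reads carrying exactly
  the intended edits / all reads; indel frequency = indel reads / all
  reads; training tables with indel discard, a strict 100-read replicate
  filter, replicate summing and add-one smoothing of every edited
  outcome.
- **Motif model** (`fitMotifModel`, `weightsToLogoMatrix`): logistic
  regression of fractional efficiencies on one-hot flanking-context
  features around targeted Cs in the editing window; mean-centered weight
  matrices ready for sequence-logo rendering.
- **Efficiency model** (`trainEfficiencyModel`, `predictEfficiency`):
  per-position ensembles of nine feed-forward networks (window sizes 7,
  9, 11 × three seeds) over a shared 16-dimensional nucleotide embedding,
  combined by softmax-normalized learned weights; sigmoid output, 30%
  dropout, MSE loss, validation-best checkpointing.
- **Proportion model** (`jointFromMarginals`, `buildChain`,
  `outcomeProportions`, `estimateAdjacentOdds`): per-position Bernoulli
  marginals tied together by adjacent-pair odds ratios
  c = p11·p00/(p01·p10) into the chain-factorized joint
  p(X1)·p(X2|X1)⋯p(Xn|Xn−1); exact enumeration of all edit patterns for
  up to 12 substrate Cs; Mantel–Haenszel pooling of c across sites.
- **Synthetic library generator** (`simulateLibrary`, `simulateReads`,
  `simulateSiteReads`): guide libraries with planted motif and window
  effects, negative-binomial coverage, indels, bystanders and correlated
  co-editing, with exported ground truth.
- **Evaluation** (`split613`, `split41`, `trisectionCV`,
  `benchmarkPredictions`): seeded by-site splits (6:1:3, 4:1), trisection
  cross-validation with a 10% validation hold-out, Pearson R / RMSE in
  pooled or per-position-averaged mode.
- A thin command-line front end at `inst/scripts/cgbe`
  (simulate / quantify / assemble / fit-motif / train-efficiency /
  predict / train-proportion / predict-proportions / evaluate / demo).

See the vignette `vignettes/cgbe-outcome-modeling.Rmd` for the models,
their assumptions and the numerical choices.

## Worked example

Simulate a small library, assemble training labels, train the efficiency
ensemble, and predict a held-out site:

```r
library(cgbesmart)

cfg <- simConfig(nSites = 400, seed = 7, replicates = 1)
lib <- simulateLibrary(cfg)
counts <- simulateReads(lib$sites, lib$truth, cfg)
asm <- assembleTrainingTable(counts, lib$sites)

sp <- split613(unique(asm$labels$site_id), seed = 7)
model <- trainEfficiencyModel(lib$sites, asm$labels, sp$train, sp$val,
                              efficiencyConfig(seed = 7, epochs = 20))
model
#> EfficiencyEnsemble: 20 position ensembles x 9 base models; embedding dim 16
#>   best epoch: 19 of 20 ; validation R = 0.9775

pred <- predictEfficiency(model, lib$sites[sp$test[1]])
head(subset(pred, !is.na(efficiency)), 3)
#>     site_id position efficiency
#> 2 site00045        2  0.4878106
#> 3 site00045        3  0.3111805
#> 7 site00045        7  0.5295202

tru <- lib$truth$efficiency
names(tru)[3] <- "efficiency"
benchmarkPredictions(predictEfficiency(model, lib$sites[sp$test]),
                     tru[tru$site_id %in% sp$test, ], "pooled")
#> $r
#> [1] 0.9821692
#>
#> $rmse
#> [1] 0.03317168
#>
#> $n
#> [1] 615
```

`pred` holds one row per protospacer position 1–20; positions without a
reference C are `NA`. The benchmark's `r` is the pooled Pearson
correlation between predicted and true per-position efficiencies over the
615 held-out (site, position) pairs; ≈0.98 already at this small training
size. The chain model then turns the predicted marginals into outcome
proportions:

```r
oddsTab <- estimateAdjacentOdds(asm$counts, lib$sites)
ch <- siteChain(lib$sites[sp$test[1]], pred, oddsTab)
round(sort(outcomeProportions(ch), decreasing = TRUE), 3)[1:4]
#>   REF    2G   10G    7G
#> 0.122 0.079 0.073 0.066
```

i.e. for this site the single most likely read-level outcome is still the
unedited sequence (12.2% of non-indel reads), followed by the lone edits
at positions 2 and 10; the remaining mass spreads over multi-edit
patterns.

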