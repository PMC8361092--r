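# End-to-end orchestration: simulate -> write/read -> assemble -> fit
# motif -> train efficiency ensemble -> estimate odds -> predict
# efficiencies and outcome proportions -> evaluate. Every stochastic step
# receives a seed derived from the single pipeline seed; artifacts and a
# metrics JSON are written to the output directory.

# stable short hash of the configuration for artifact stamping
.configHash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v)
    paste(format(v, digits = 15), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  sprintf("%08x", .deriveSeed(0L, s))
}

#' Run the full demonstration pipeline on a simulated library
#'
#' Simulates a library, round-trips it through the TSV formats, assembles
#' the filtered and smoothed training table, fits the motif model on the
#' editing-window labels, trains the efficiency ensemble on a seeded
#' 6:1:3 split, estimates pooled adjacent odds ratios, predicts held-out
#' efficiencies and outcome proportions, and writes benchmarking metrics.
#'
#' @param outDir output directory (created if needed).
#' @param seed master seed for every stochastic step.
#' @param nSites number of simulated sites.
#' @param simOverrides named list overriding \code{\link{simConfig}}
#'   defaults.
#' @param trainOverrides named list overriding
#'   \code{\link{efficiencyConfig}} defaults.
#' @param verbose print progress.
#' @return list of metrics (also written to \code{metrics.json}),
#'   invisibly.
#' @export
runPipeline <- function(outDir, seed = 1L, nSites = 500L,
                        simOverrides = list(), trainOverrides = list(),
                        verbose = TRUE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)

  scfg <- do.call(simConfig, c(list(nSites = nSites, seed = seed),
                               simOverrides))
  hash <- .configHash(scfg)
  say("simulating library (", nSites, " sites, config ", hash, ")")
  lib <- simulateLibrary(scfg)
  counts <- simulateReads(lib$sites, lib$truth, scfg)

  writeSiteTable(lib$sites, file.path(outDir, "sites.tsv"))
  writeOutcomeTable(counts, file.path(outDir, "outcomes.tsv"))
  writeTruth(lib$truth, file.path(outDir, "truth.tsv"))
  sites <- readSiteTable(file.path(outDir, "sites.tsv"))
  counts <- readOutcomeTable(file.path(outDir, "outcomes.tsv"))

  say("assembling training table")
  asm <- assembleTrainingTable(counts, sites)
  labels <- asm$labels

  split <- split613(unique(labels$site_id), seed = .deriveSeed(seed,
                                                               "split"))
  trainLab <- labels[labels$site_id %in% split$train, , drop = FALSE]

  say("fitting motif model")
  mf <- motifFeatures(sites, trainLab, k = 3L)
  motif <- fitMotifModel(mf$X, mf$y)
  writeLogoMatrix(motif, file.path(outDir, "motif_logo.tsv"))

  say("training efficiency ensemble")
  tcfg <- do.call(efficiencyConfig,
                  c(list(seed = .deriveSeed(seed, "train") %% 100000L),
                    trainOverrides))
  model <- trainEfficiencyModel(sites, labels, split$train, split$val,
                                tcfg, verbose = verbose)

  say("estimating adjacent odds ratios")
  trainPooled <- countsTable(asm$counts)
  trainPooled <- trainPooled[trainPooled$site_id %in% split$train, ,
                             drop = FALSE]
  oddsTab <- estimateAdjacentOdds(
    OutcomeCounts(trainPooled$site_id, trainPooled$replicate,
                  trainPooled$pattern, trainPooled$count), sites)
  write.table(oddsTab, file.path(outDir, "adjacent_odds.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  say("predicting held-out sites")
  testSites <- sites[split$test]
  pred <- predictEfficiency(model, testSites)
  writePredictions(pred, file.path(outDir, "pred_efficiency.tsv"))

  props <- list()
  for (id in head(split$test, 200L)) {
    ch <- siteChain(sites[id], pred, oddsTab)
    if (is.null(ch) || length(ch@positions) > 12L) next
    pr <- outcomeProportions(ch)
    props[[id]] <- data.frame(site_id = id, pattern = names(pr),
                              probability = as.numeric(pr))
  }
  if (length(props))
    writeProportions(do.call(rbind, props),
                     file.path(outDir, "pred_proportions.tsv"))

  obs <- labels[labels$site_id %in% split$test, , drop = FALSE]
  bench <- benchmarkPredictions(pred, obs, "pooled")
  truthDf <- lib$truth$efficiency
  names(truthDf)[names(truthDf) == "p_true"] <- "efficiency"
  benchTruth <- benchmarkPredictions(
    pred, truthDf[truthDf$site_id %in% split$test, ], "pooled")
  motifPred <- data.frame(site_id = mf$site_id, position = mf$position,
                          efficiency = predictMotif(motif, mf$X))
  motifBench <- benchmarkPredictions(motifPred, trainLab, "pooled")

  metrics <- list(config_hash = hash, seed = seed, n_sites = nSites,
                  n_train = length(split$train),
                  n_val = length(split$val),
                  n_test = length(split$test),
                  dropped_replicates = nrow(asm$dropped),
                  efficiency_test_r = bench$r,
                  efficiency_test_rmse = bench$rmse,
                  efficiency_test_r_vs_truth = benchTruth$r,
                  motif_train_r = motifBench$r,
                  best_epoch = model@bestEpoch)
  jsonlite::write_json(metrics, file.path(outDir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done; metrics written to ", file.path(outDir, "metrics.json"))
  invisible(metrics)
}
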