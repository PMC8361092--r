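# small architectures are used throughout these unit tests; the
# full-size default architecture is exercised by the recovery tests in
# test-acceptance.R

smallCfg <- function(...) {
  efficiencyConfig(hidden = c(32L, 16L), batchSize = 128L, ...)
}

smallLibrary <- function(nSites = 120, seed = 31, ...) {
  cfg <- simConfig(nSites = nSites, seed = seed, coverageMean = 800,
                   indelRate = 0, adjacentOdds = 1, replicates = 1, ...)
  lib <- simulateLibrary(cfg)
  oc <- simulateReads(lib$sites, lib$truth, cfg)
  asm <- assembleTrainingTable(oc, lib$sites)
  list(sites = lib$sites, labels = asm$labels, truth = lib$truth)
}

test_that("extractWindow centers on the queried position with PAD at the edges", {
  site <- makeSite(protoWithCs(10))
  proto <- protospacerSeq(site, withPAM = TRUE)
  w7 <- extractWindow(site, 10, 7)
  expect_equal(paste(w7, collapse = ""), substr(proto, 7, 13))
  # position 20 spans into the PAM
  w20 <- extractWindow(site, 20, 7)
  expect_equal(paste(w20, collapse = ""), substr(proto, 17, 23))

  # exactly 5 nt left flank: no PAD needed for w = 11 at position 1
  tight <- TargetSiteSet("t", paste0("ATGAT", protoWithCs(5), "AGG",
                                     "TGATGATGAT"), 6L)
  expect_false("PAD" %in% extractWindow(tight, 1, 11))
  # a wider window does run off the sequence
  w13 <- extractWindow(tight, 1, 13)
  expect_equal(w13[1], "PAD")

  expect_error(extractWindow(site, 10, 8), "odd")
  expect_error(extractWindow(site, 21, 7), "1-20")
})

test_that("training rejects bad inputs", {
  d <- smallLibrary(nSites = 30)
  ids <- unique(d$labels$site_id)
  expect_error(trainEfficiencyModel(d$sites, d$labels, ids, character(0)),
               "validation set is empty")
  expect_error(trainEfficiencyModel(d$sites, d$labels, ids, ids[1]),
               "disjoint")
  badLab <- rbind(d$labels[, 1:3],
                  data.frame(site_id = ids[1], position = 0L,
                             efficiency = 0.5))
  badLab$position[nrow(badLab)] <-
    setdiff(1:20, d$labels$position[d$labels$site_id == ids[1]])[1]
  expect_error(trainEfficiencyModel(d$sites, badLab, ids[-1], ids[1]),
               "non-C")
})

test_that("identical seeds give identical validation curves and predictions", {
  d <- smallLibrary(nSites = 60)
  ids <- unique(d$labels$site_id)
  sp <- split613(ids, seed = 3)
  cfg <- smallCfg(seed = 5, epochs = 3L)
  m1 <- trainEfficiencyModel(d$sites, d$labels, sp$train, sp$val, cfg)
  m2 <- trainEfficiencyModel(d$sites, d$labels, sp$train, sp$val, cfg)
  expect_identical(trainingHistory(m1), trainingHistory(m2))
  p1 <- predictEfficiency(m1, d$sites[sp$test])
  p2 <- predictEfficiency(m2, d$sites[sp$test])
  expect_identical(p1, p2)
  # eval mode is deterministic on repeated calls too
  expect_identical(p1, predictEfficiency(m1, d$sites[sp$test]))
})

test_that("predictions are bounded, NA off substrate, and combination weights normalize", {
  d <- smallLibrary(nSites = 60, seed = 8)
  ids <- unique(d$labels$site_id)
  sp <- split613(ids, seed = 3)
  m <- trainEfficiencyModel(d$sites, d$labels, sp$train, sp$val,
                            smallCfg(seed = 2, epochs = 2L))
  pred <- predictEfficiency(m, d$sites)
  st <- siteTable(d$sites)
  proto <- substr(st$sequence, st$protospacer_start,
                  st$protospacer_start + 19L)
  isC <- substr(proto[match(pred$site_id, st$site_id)], pred$position,
                pred$position) == "C"
  expect_true(all(is.na(pred$efficiency[!isC])))
  trained <- pred$position %in% as.integer(names(m@positions))
  expect_true(all(pred$efficiency[isC & trained] > 0 &
                    pred$efficiency[isC & trained] < 1))
  w <- combinationWeights(m)
  expect_equal(unname(rowSums(w)), rep(1, nrow(w)))
  expect_true(all(w >= 0))

  # a site with no protospacer C gets NA everywhere
  noC <- TargetSiteSet("noc", paste0("ATGATGATGA",
                                     paste(rep("A", 20), collapse = ""),
                                     "AGGTGATGATGAT"), 11L)
  expect_true(all(is.na(predictEfficiency(m, noC)$efficiency)))
})

test_that("the ensemble prediction equals the weighted average of re-computed base models", {
  d <- smallLibrary(nSites = 40, seed = 13)
  ids <- unique(d$labels$site_id)
  sp <- split613(ids, seed = 3)
  m <- trainEfficiencyModel(d$sites, d$labels, sp$train, sp$val,
                            smallCfg(seed = 2, epochs = 2L))
  site <- d$sites[ids[1]]
  p <- substratePositions(site)[1]
  pp <- m@positions[[as.character(p)]]
  expect_false(is.null(pp))

  # independent re-computation from stored parameters
  wvec <- rep(m@config$windows, each = m@config$replicatesPerWindow)
  alpha <- pp$alpha
  wts <- exp(alpha - max(alpha)); wts <- wts / sum(wts)
  manual <- 0
  for (b in seq_along(wvec)) {
    syms <- extractWindow(site, p, wvec[b])
    x <- as.vector(t(m@embedding[syms, , drop = FALSE]))
    br <- pp$branches[[b]]
    h1 <- pmax(drop(x %*% br$W1) + br$b1, 0)
    h2 <- pmax(drop(h1 %*% br$W2) + br$b2, 0)
    manual <- manual + wts[b] * 1 / (1 + exp(-(sum(h2 * br$W3) + br$b3)))
  }
  pred <- predictEfficiency(m, site)
  expect_equal(pred$efficiency[pred$position == p], manual,
               tolerance = 1e-12)
})

test_that("predictions are invariant to flank content outside the widest window", {
  d <- smallLibrary(nSites = 40, seed = 17)
  ids <- unique(d$labels$site_id)
  sp <- split613(ids, seed = 3)
  m <- trainEfficiencyModel(d$sites, d$labels, sp$train, sp$val,
                            smallCfg(seed = 2, epochs = 2L))
  st <- siteTable(d$sites[ids[1]])
  seq2 <- st$sequence
  substr(seq2, 1, 1) <- if (substr(seq2, 1, 1) == "A") "T" else "A"
  alt <- TargetSiteSet(st$site_id, seq2, st$protospacer_start)
  p1 <- predictEfficiency(m, d$sites[ids[1]])
  p2 <- predictEfficiency(m, alt)
  # sequence index 1 is more than 5 nt away from protospacer position 10
  expect_identical(p1$efficiency[p1$position >= 10],
                   p2$efficiency[p2$position >= 10])
})

test_that("constant labels drive held-out predictions to the constant", {
  d <- smallLibrary(nSites = 200, seed = 23)
  lab <- d$labels
  lab$efficiency <- 0.25
  ids <- unique(lab$site_id)
  sp <- split613(ids, seed = 3)
  m <- trainEfficiencyModel(d$sites, lab, sp$train, sp$val,
                            smallCfg(seed = 4, epochs = 80L, lr = 3e-3))
  pred <- predictEfficiency(m, d$sites[sp$test])
  got <- pred$efficiency[!is.na(pred$efficiency)]
  expect_lt(max(abs(got - 0.25)), 0.02)
})
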