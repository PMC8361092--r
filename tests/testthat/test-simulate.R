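test_that("the simulator is deterministic and plants the configured structure", {
  cfg <- simConfig(nSites = 40, seed = 77)
  a <- simulateLibrary(cfg)
  b <- simulateLibrary(cfg)
  expect_identical(siteTable(a$sites), siteTable(b$sites))
  expect_identical(a$truth$efficiency, b$truth$efficiency)
  expect_equal(length(a$sites), 40L)
  expect_identical(countsTable(simulateReads(a$sites, a$truth, cfg)),
                   countsTable(simulateReads(b$sites, b$truth, cfg)))

  # A/T neighbors lift the true efficiency (WCW > GCG contexts)
  te <- a$truth$efficiency
  st <- siteTable(a$sites)
  neigh <- vapply(seq_len(nrow(te)), function(i) {
    s <- st[st$site_id == te$site_id[i], ]
    ctr <- s$protospacer_start + te$position[i] - 1L
    paste0(substr(s$sequence, ctr - 1, ctr - 1),
           substr(s$sequence, ctr + 1, ctr + 1))
  }, character(1))
  wcw <- grepl("^[AT][AT]$", neigh)
  gcg <- grepl("^[CG][CG]$", neigh)
  expect_gt(mean(te$p_true[wcw]), mean(te$p_true[gcg]))

  # window effect: positions 4-7 higher on average
  expect_gt(mean(te$p_true[te$position %in% 4:7]),
            mean(te$p_true[!te$position %in% 4:7]))

  expect_error(simConfig(nSites = 0), "nSites")
  expect_error(simConfig(coverageMean = 0.5), "coverage")
})

test_that("per-site random streams do not depend on site order", {
  cfg <- simConfig(nSites = 12, seed = 5, replicates = 1)
  lib <- simulateLibrary(cfg)
  oc1 <- countsTable(simulateReads(lib$sites, lib$truth, cfg))
  perm <- rev(seq_len(length(lib$sites)))
  oc2 <- countsTable(simulateReads(lib$sites[perm], lib$truth, cfg))
  o1 <- oc1[order(oc1$site_id, oc1$pattern), ]
  o2 <- oc2[order(oc2$site_id, oc2$pattern), ]
  expect_equal(o1$count, o2$count)
  expect_equal(o1$pattern, o2$pattern)
})

test_that("planted adjacent odds ratios surface in the sampled counts", {
  site <- makeSite(protoWithCs(c(5, 6)))
  mkTruth <- function(cc) list(
    efficiency = data.frame(site_id = "s1", position = c(5L, 6L),
                            p_true = 0.5),
    adjacentOdds = cc, indelRate = 0, bystanderRate = 0)
  cfg <- simConfig(nSites = 1, seed = 19, coverageMean = 5000,
                   coverageDispersion = 1e6, indelRate = 0,
                   replicates = 1)

  ocInd <- simulateReads(site, mkTruth(1), cfg)
  tabInd <- estimateAdjacentOdds(ocInd, site)
  expect_lt(abs(log(tabInd$c)), 0.25)   # ~4 SE of log OR at this depth

  oc9 <- simulateReads(site, mkTruth(9), cfg)
  tab9 <- estimateAdjacentOdds(oc9, site)
  expect_gt(tab9$c, 6.5)
  expect_lt(tab9$c, 12.5)
})

test_that("degenerate truth gives all-REF outcome tables", {
  site <- makeSite(protoWithCs(c(5, 6)))
  truth <- list(efficiency = data.frame(site_id = "s1",
                                        position = c(5L, 6L),
                                        p_true = 0),
                adjacentOdds = 1, indelRate = 0, bystanderRate = 0)
  cfg <- simConfig(nSites = 1, seed = 3, coverageMean = 500,
                   indelRate = 0, replicates = 1)
  oc <- suppressWarnings(simulateReads(site, truth, cfg))
  d <- countsTable(oc)
  expect_equal(unique(d$pattern), "REF")
})

test_that("read-level simulation respects orientation and classifies back to truth", {
  fw <- makeSite(protoWithCs(6), id = "s1")
  rv <- makeSite(protoWithCs(6), id = "s1", strand = "reverse")
  truth <- function(id) list(
    efficiency = data.frame(site_id = id, position = 6L, p_true = 0.4),
    adjacentOdds = 1, indelRate = 0.1, bystanderRate = 0)
  cfg <- simConfig(nSites = 1, seed = 10, coverageMean = 400,
                   replicates = 1)

  rf <- simulateSiteReads(fw, truth("s1"), cfg)
  rr <- simulateSiteReads(rv, truth("s1"), cfg)
  # same derived stream up to orientation: reverse reads are the
  # reverse complements of the forward-frame reads
  expect_identical(orientToForward(rr, "reverse"), rf)

  calls <- classifyReads(orientToForward(rr, "reverse"), rv)
  expect_setequal(unique(calls$class),
                  c("unedited", "substitution_pattern", "indel"))
  eff <- onTargetEfficiency(calls, "6G")
  expect_lt(abs(eff - 0.9 * 0.4), 4 * sqrt(0.36 * 0.64 / length(rr)) + 0.02)
})
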