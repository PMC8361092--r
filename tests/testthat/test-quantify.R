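test_that("orientToForward reverse-complements reverse reads and is stable", {
  expect_equal(orientToForward("ACCGGT", "forward"), "ACCGGT")
  expect_equal(orientToForward("CCGGT", "reverse"), "ACCGG")
  once <- orientToForward("CCGGT", "reverse")
  expect_equal(orientToForward(once, "forward"), once)
  expect_error(orientToForward("ACGT", "up"), "orientation")
})

test_that("classifyReads separates unedited, substitutions and indels", {
  site <- makeSite(protoWithCs(c(6, 8)))
  ref <- siteTable(site)$sequence

  edited <- ref
  substr(edited, 11 + 5, 11 + 5) <- "G"        # protospacer position 6
  bystander <- ref
  substr(bystander, 11 + 7, 11 + 7) <- "T"     # position 8, C->T
  shorter <- paste0(substr(ref, 1, 14), substr(ref, 16, nchar(ref)))

  calls <- classifyReads(c(ref, edited, bystander, shorter), site)
  expect_equal(calls$class, c("unedited", "substitution_pattern",
                              "substitution_pattern", "indel"))
  expect_equal(calls$subs, c("", "6G", "8T", ""))

  expect_error(classifyReads(substr(ref, 1, 20), site), "cover")
})

test_that("deletions in the far flank do not flag indel calls", {
  site <- makeSite(protoWithCs(6))
  ref <- siteTable(site)$sequence
  clipped <- substr(ref, 1, nchar(ref) - 3L)   # right-flank deletion
  calls <- classifyReads(clipped, site)
  expect_equal(calls$class, "unedited")
})

test_that("on-target efficiency and indel frequency follow the read-count formulas", {
  calls <- makeCalls(
    c(rep("substitution_pattern", 3), "substitution_pattern",
      rep("indel", 2), rep("unedited", 4)),
    c(rep("6G", 3), "6G+8G", "", "", rep("", 4)))
  expect_equal(onTargetEfficiency(calls, "6G"), 0.3)
  expect_equal(indelFrequency(calls), 0.2)

  allRef <- makeCalls(rep("unedited", 5))
  expect_equal(onTargetEfficiency(allRef, "6G"), 0)
  expect_equal(indelFrequency(allRef), 0)
  allHit <- makeCalls(rep("substitution_pattern", 4), "6G")
  expect_equal(onTargetEfficiency(allHit, "6G"), 1)
  expect_equal(indelFrequency(makeCalls(rep("indel", 3))), 1)

  expect_error(onTargetEfficiency(allRef[0, ], "6G"), "empty")
  expect_error(indelFrequency(allRef[0, ]), "empty")

  # class fractions partition the reads
  mixed <- makeCalls(c("substitution_pattern", "substitution_pattern",
                       "indel", "unedited"), c("6G", "6G+8T", "", ""))
  onT <- onTargetEfficiency(mixed, "6G")
  byst <- mean(mixed$class == "substitution_pattern" &
                 mixed$subs != "6G")
  unod <- mean(mixed$class == "unedited")
  expect_equal(onT + byst + indelFrequency(mixed) + unod, 1)
})

test_that("assembleTrainingTable filters, sums, and smooths as specified", {
  site <- makeSite(protoWithCs(6))
  # both replicates below 100 post-indel-removal reads: site dropped
  ocLow <- OutcomeCounts(rep("s1", 4), c("r1", "r1", "r2", "r2"),
                         c("REF", "6G", "REF", "6G"), c(50, 10, 60, 20))
  asmLow <- suppressMessages(assembleTrainingTable(ocLow, site))
  expect_equal(nrow(asmLow$labels), 0L)
  expect_equal(nrow(asmLow$dropped), 2L)

  # r1 (120 reads) kept, r2 (80) dropped; replicate summing + smoothing
  oc <- OutcomeCounts(rep("s1", 4), c("r1", "r1", "r2", "r2"),
                      c("REF", "6G", "REF", "6G"), c(90, 30, 60, 20))
  asm <- suppressMessages(assembleTrainingTable(oc, site))
  d <- countsTable(asm$counts)
  expect_equal(d$count[d$pattern == "6G"], 31)  # 30 + add-one
  expect_equal(asm$labels$efficiency, 31 / (121))
  expect_equal(asm$labels$coverage, 120)

  # indel reads removed before the filter; replicate order irrelevant
  oc2 <- OutcomeCounts(rep("s1", 3), rep("r1", 3),
                       c("REF", "6G", "INDEL"), c(90, 30, 50))
  oc2r <- OutcomeCounts(rep("s1", 3), rep("r1", 3),
                        c("INDEL", "6G", "REF"), c(50, 30, 90))
  a1 <- assembleTrainingTable(oc2, site)
  a2 <- assembleTrainingTable(oc2r, site)
  expect_equal(a1$labels, a2$labels)
  expect_false("INDEL" %in% countsTable(a1$counts)$pattern)

  # an unobserved edited outcome gets count 1 after smoothing
  ocZero <- OutcomeCounts("s1", "r1", "REF", 500)
  asmZero <- assembleTrainingTable(ocZero, site)
  dz <- countsTable(asmZero$counts)
  expect_equal(dz$count[dz$pattern == "6G"], 1)
})

test_that("windowFilter keeps positions 4-7 above 100x coverage, strictly", {
  lab <- data.frame(site_id = "s", position = c(3, 5, 5, 7),
                    efficiency = 0.1, coverage = c(500, 100, 101, 2000))
  kept <- windowFilter(lab)
  expect_equal(kept$position, c(5, 7))
  expect_equal(kept$coverage, c(101, 2000))
})

test_that("labels converge to the generator truth with coverage", {
  cfg <- simConfig(nSites = 60, seed = 42, coverageMean = 2000,
                   coverageDispersion = 50, indelRate = 0,
                   adjacentOdds = 1, replicates = 1)
  lib <- simulateLibrary(cfg)
  oc <- simulateReads(lib$sites, lib$truth, cfg)
  asm <- assembleTrainingTable(oc, lib$sites)
  m <- merge(asm$labels, lib$truth$efficiency,
             by = c("site_id", "position"))
  # small additive slack for the deterministic add-one smoothing shift
  band <- 4 * sqrt(m$p_true * (1 - m$p_true) / m$coverage) + 0.01
  expect_gte(mean(abs(m$efficiency - m$p_true) <= band), 0.99)
})
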