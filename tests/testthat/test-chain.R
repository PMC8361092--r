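test_that("estimateC applies the odds-ratio formula and rejects zero cells", {
  expect_equal(estimateC(c(p11 = 0.4, p10 = 0.1, p01 = 0.1, p00 = 0.4)),
               16)
  expect_equal(estimateC(c(p11 = 3, p10 = 1, p01 = 1, p00 = 3)), 9)
  # independent pair: c = 1
  pA <- 0.3; pB <- 0.7
  expect_equal(estimateC(c(p11 = pA * pB, p10 = pA * (1 - pB),
                           p01 = (1 - pA) * pB,
                           p00 = (1 - pA) * (1 - pB))), 1)
  expect_error(estimateC(c(p11 = 0, p10 = .4, p01 = .3, p00 = .3)),
               "smoothing")
})

test_that("jointFromMarginals hits margins, odds ratio and the closed form", {
  j <- jointFromMarginals(0.3, 0.2, 1)
  expect_equal(unname(j["p11"]), 0.06, tolerance = 1e-12)
  j2 <- jointFromMarginals(0.5, 0.5, 9)
  expect_equal(unname(j2["p11"]), 0.375, tolerance = 1e-12)

  set.seed(4)
  for (i in 1:200) {
    pA <- runif(1, .02, .98); pB <- runif(1, .02, .98)
    cc <- exp(runif(1, log(.05), log(20)))
    j <- jointFromMarginals(pA, pB, cc)
    expect_equal(unname(j["p11"] + j["p10"]), pA, tolerance = 1e-12)
    expect_equal(unname(j["p11"] + j["p01"]), pB, tolerance = 1e-12)
    expect_equal(estimateC(j) / cc, 1, tolerance = 1e-9)
    expect_true(j["p11"] > max(0, pA + pB - 1) && j["p11"] < min(pA, pB))
    # agreement with the independent root-search oracle
    expect_equal(unname(j["p11"]), unname(oracleJoint(pA, pB, cc)["p11"]),
                 tolerance = 1e-9)
  }

  # p11 strictly increasing in c at fixed margins
  p11s <- vapply(c(0.2, 0.5, 1, 2, 5, 20), function(cc)
    jointFromMarginals(0.35, 0.6, cc)[["p11"]], numeric(1))
  expect_true(all(diff(p11s) > 0))

  expect_error(jointFromMarginals(0, 0.5, 2), "strictly")
  expect_error(jointFromMarginals(0.5, 0.5, -1), "positive")
})

test_that("buildChain preserves marginals through the forward recursion", {
  ch <- buildChain(c(0.3), numeric(0), positions = 5L)
  pr <- outcomeProportions(ch)
  expect_equal(unname(pr["5G"]), 0.3)
  expect_equal(unname(pr["REF"]), 0.7)

  set.seed(11)
  for (i in 1:25) {
    n <- sample(2:6, 1)
    m <- runif(n, 0.05, 0.95)
    cc <- exp(runif(n - 1, log(.1), log(10)))
    ch <- buildChain(m, cc)
    # conditional rows sum to 1
    for (cm in ch@conditionals) expect_equal(rowSums(cm),
                                             c(`0` = 1, `1` = 1))
    pr <- outcomeProportions(ch)
    expect_equal(sum(pr), 1, tolerance = 1e-9)
    pos <- ch@positions
    for (k in seq_len(n)) {
      marg <- sum(pr[vapply(patternPositions(names(pr)),
                            function(q) pos[k] %in% q, logical(1))])
      expect_equal(marg, m[k], tolerance = 1e-9)
    }
  }

  # all c = 1 reduces to the independent product model
  m <- c(0.2, 0.5, 0.8)
  pr <- outcomeProportions(buildChain(m, c(1, 1)))
  expect_equal(unname(pr["REF"]), prod(1 - m), tolerance = 1e-12)
  expect_equal(unname(pr["1G+2G+3G"]), prod(m), tolerance = 1e-12)

  expect_warning(buildChain(c(0, 0.5), 1), "clipped")
  pr0 <- suppressWarnings(outcomeProportions(buildChain(c(0, 0), 1)))
  expect_equal(unname(pr0["REF"]), 1, tolerance = 1e-6)
})

test_that("n = 2 chain equals the bivariate joint and the worked case", {
  pr <- outcomeProportions(buildChain(c(0.5, 0.5), 9))
  expect_equal(unname(pr[c("1G+2G", "REF", "1G", "2G")]),
               c(0.375, 0.375, 0.125, 0.125), tolerance = 1e-12)
})

test_that("enumeration matches the reverse-factorization oracle", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(3:6, 1)
    m <- runif(n, 0.05, 0.95)
    cc <- exp(runif(n - 1, log(.1), log(10)))
    pr <- outcomeProportions(buildChain(m, cc))
    orc <- oracleChainProbs(m, cc)
    expect_lt(max(abs(pr[names(orc)] - orc)), 1e-9)
  }
  expect_error(outcomeProportions(buildChain(runif(14, .4, .6),
                                             rep(1, 13))),
               "sampleChain")
})

test_that("pooled adjacent odds are estimated per absolute position pair", {
  # two sites sharing the (6,8) substrate pair, counts chosen for c = 9
  site <- makeSite(protoWithCs(c(6, 8)), id = "sA")
  oc <- OutcomeCounts(rep("sA", 4), rep("r", 4),
                      c("6G+8G", "6G", "8G", "REF"), c(30, 10, 10, 30))
  tab <- estimateAdjacentOdds(oc, site)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$posA, 6); expect_equal(tab$posB, 8)
  expect_equal(tab$c, 9)

  # pooling across two sites with the same pair
  sites2 <- TargetSiteSet(c("sA", "sB"),
                          rep(siteTable(site)$sequence, 2), c(11L, 11L))
  oc2 <- OutcomeCounts(rep(c("sA", "sB"), each = 4), rep("r", 8),
                       rep(c("6G+8G", "6G", "8G", "REF"), 2),
                       c(30, 10, 10, 30, 3, 1, 1, 3))
  tab2 <- estimateAdjacentOdds(oc2, sites2)
  expect_equal(tab2$n11, 33)
  expect_equal(tab2$c, 33 * 33 / (11 * 11))
})

test_that("siteChain excludes non-C positions and uses pooled odds", {
  site <- makeSite(protoWithCs(c(4, 6)))
  marg <- data.frame(site_id = "s1", position = 1:20,
                     efficiency = NA_real_)
  marg$efficiency[marg$position %in% c(4, 6)] <- c(0.5, 0.5)
  oddsTab <- data.frame(posA = 4, posB = 6, n11 = 1, n10 = 1, n01 = 1,
                        n00 = 1, c = 9)
  ch <- siteChain(site, marg, oddsTab)
  expect_equal(ch@positions, c(4L, 6L))
  expect_equal(ch@odds, 9)
  pr <- outcomeProportions(ch)
  expect_equal(unname(pr["4G+6G"]), 0.375, tolerance = 1e-12)
  # unseen pair falls back to independence
  ch2 <- siteChain(site, marg, oddsTab[0, ])
  expect_equal(ch2@odds, 1)
})
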