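# Chain-factorized joint model over per-position edit indicators: combine
# per-position marginals with adjacent-pair odds ratios
# c = p11 p00 / (p01 p10) into the forward-factorized joint
# p(X1) p(X2|X1) ... p(Xn|Xn-1), from which the proportion of every edit
# pattern is enumerated.

#' Odds ratio of an adjacent position pair
#'
#' Computes c = p11 p00 / (p01 p10) from the four joint cells. Raw counts
#' are accepted and normalized (the odds ratio is scale-invariant).
#'
#' @param pairCounts numeric vector with named elements \code{p11},
#'   \code{p10}, \code{p01}, \code{p00}, all strictly positive after
#'   smoothing.
#' @return positive numeric odds ratio.
#' @export
estimateC <- function(pairCounts) {
  need <- c("p11", "p10", "p01", "p00")
  if (!all(need %in% names(pairCounts)))
    stop("pairCounts needs elements p11, p10, p01, p00", call. = FALSE)
  x <- as.numeric(pairCounts[need])
  if (any(x <= 0))
    stop("zero cell in pair counts; apply add-one smoothing upstream",
         call. = FALSE)
  (x[1] * x[4]) / (x[3] * x[2])
}

#' Bivariate Bernoulli joint from margins and odds ratio
#'
#' Returns the unique 2x2 joint with margins (pA, pB) and odds ratio c:
#' for c = 1 the independence product pA pB; otherwise the root of
#' c (pA - p11)(pB - p11) = p11 (1 - pA - pB + p11) that lies strictly
#' within the Frechet bounds max(0, pA + pB - 1) < p11 < min(pA, pB).
#' The quadratic has the closed-form (Plackett) solution
#' p11 = (b - sqrt(b^2 - 4 c (c-1) pA pB)) / (2 (c-1)) with
#' b = 1 + (c-1)(pA + pB); bisection is used as a fallback when the
#' discriminant is numerically marginal.
#'
#' @param pA,pB marginal probabilities in (0,1).
#' @param c positive odds ratio.
#' @return named numeric vector \code{p11}, \code{p10}, \code{p01},
#'   \code{p00}; margins reproduced to 1e-12, odds ratio to 1e-9.
#' @export
jointFromMarginals <- function(pA, pB, c) {
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    stop("margins must lie strictly in (0,1)", call. = FALSE)
  if (c <= 0) stop("odds ratio must be positive", call. = FALSE)
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  if (abs(c - 1) < 1e-12) {
    p11 <- pA * pB
  } else {
    b <- 1 + (c - 1) * (pA + pB)
    disc <- b^2 - 4 * c * (c - 1) * pA * pB
    if (disc >= 0) {
      p11 <- (b - sqrt(disc)) / (2 * (c - 1))
    } else p11 <- NA_real_
    if (!is.finite(p11) || p11 <= lo || p11 >= hi) {
      f <- function(x) c * (pA - x) * (pB - x) - x * (1 - pA - pB + x)
      eps <- 1e-15 * (hi - lo)
      root <- tryCatch(
        stats::uniroot(f, c(lo + eps, hi - eps), tol = 1e-14)$root,
        error = function(e)
          stop("no admissible root within the Frechet bounds ",
               "(internal error)", call. = FALSE))
      p11 <- root
    }
  }
  c(p11 = p11, p10 = pA - p11, p01 = pB - p11, p00 = 1 - pA - pB + p11)
}

#' Build the chain model from marginals and adjacent odds ratios
#'
#' Conditional tables are derived per adjacent pair from
#' \code{\link{jointFromMarginals}}: p(Xi=1 | Xi-1=1) = p11 / pA and
#' p(Xi=1 | Xi-1=0) = (pB - p11) / (1 - pA), so the forward recursion over
#' the chain reproduces every input marginal exactly.
#'
#' @param marginals numeric vector of per-position editing probabilities;
#'   values at exactly 0 or 1 are clipped to [1e-9, 1 - 1e-9] with a
#'   warning.
#' @param odds numeric vector of adjacent odds ratios, length n - 1.
#' @param positions integer protospacer positions (default 1..n).
#' @return a \linkS4class{ChainModel}.
#' @export
buildChain <- function(marginals, odds = numeric(0),
                       positions = seq_along(marginals)) {
  n <- length(marginals)
  if (n < 1L) stop("need at least one marginal", call. = FALSE)
  if (n > 1L && length(odds) != n - 1L)
    stop("need n - 1 odds ratios", call. = FALSE)
  if (any(marginals <= 0 | marginals >= 1)) {
    warning("marginals at 0 or 1 clipped to [1e-9, 1 - 1e-9]")
    marginals <- pmin(pmax(marginals, 1e-9), 1 - 1e-9)
  }
  conds <- list()
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      j <- jointFromMarginals(marginals[i], marginals[i + 1L], odds[i])
      pA <- marginals[i]
      m <- rbind(`0` = c(j["p00"], j["p01"]) / (1 - pA),
                 `1` = c(j["p10"], j["p11"]) / pA)
      colnames(m) <- c("0", "1")
      conds[[i]] <- m
    }
  }
  new("ChainModel", positions = as.integer(positions),
      marginals = as.numeric(marginals), odds = as.numeric(odds),
      conditionals = conds)
}

#' Enumerate the probability of every edit pattern
#'
#' Computes p(X1) p(X2|X1) ... p(Xn|Xn-1) for all 2^n binary patterns by
#' forward dynamic expansion. Patterns are named canonically
#' (\code{"REF"} for the empty pattern, else sorted position tokens such
#' as \code{"4G+7G"}).
#'
#' @param chain a \linkS4class{ChainModel}.
#' @param nMax largest n for exact enumeration (default 12); larger chains
#'   are an error directing to sampling.
#' @return named numeric vector over all 2^n patterns, summing to 1.
#' @export
outcomeProportions <- function(chain, nMax = 12L) {
  stopifnot(is(chain, "ChainModel"))
  n <- length(chain@positions)
  if (n > nMax)
    stop("n = ", n, " exceeds nMax = ", nMax,
         " for exact enumeration; use sampleChain()", call. = FALSE)
  states <- matrix(c(0L, 1L), ncol = 1)
  probs <- c(1 - chain@marginals[1], chain@marginals[1])
  if (n > 1L) for (i in seq_len(n - 1L)) {
    m <- chain@conditionals[[i]]
    k <- nrow(states)
    prev <- states[, i]
    probs <- c(probs * m[prev + 1L, 1L], probs * m[prev + 1L, 2L])
    states <- rbind(cbind(states, 0L), cbind(states, 1L))
  }
  nm <- apply(states, 1L, function(s) makePattern(chain@positions[s == 1L]))
  setNames(probs, nm)
}

#' Sample edit patterns from a chain model
#'
#' Forward ancestral sampling; used for chains too long for exact
#' enumeration and by the library simulator.
#'
#' @param chain a \linkS4class{ChainModel}.
#' @param n number of samples.
#' @return integer matrix (n x positions) of 0/1 indicators, columns named
#'   by protospacer position.
#' @export
sampleChain <- function(chain, n) {
  stopifnot(is(chain, "ChainModel"))
  k <- length(chain@positions)
  X <- matrix(0L, n, k, dimnames = list(NULL, chain@positions))
  X[, 1] <- as.integer(runif(n) < chain@marginals[1])
  if (k > 1L) for (i in seq_len(k - 1L)) {
    m <- chain@conditionals[[i]]
    p1 <- m[X[, i] + 1L, 2L]
    X[, i + 1L] <- as.integer(runif(n) < p1)
  }
  X
}

#' Pooled adjacent-pair odds ratios from an outcome table
#'
#' For every pair of adjacent substrate-C positions, tabulates the four
#' joint cells (both edited / only left / only right / neither, indels
#' excluded) per site and pools sites sharing the same absolute position
#' pair with the Mantel-Haenszel stratified estimator,
#' c = sum_s(n11 n00 / N) / sum_s(n10 n01 / N). Stratifying by site
#' before pooling avoids the attenuation that collapsing 2x2 tables with
#' heterogeneous marginals would introduce; for a single site it reduces
#' to the plain odds-ratio formula. Estimates are capped to [1e-4, 1e4]
#' to guard against smoothing artifacts.
#'
#' @param counts an \linkS4class{OutcomeCounts} (typically the smoothed
#'   pooled table from \code{\link{assembleTrainingTable}}).
#' @param sites the matching \linkS4class{TargetSiteSet}.
#' @return data.frame with columns \code{posA}, \code{posB} (position
#'   pair), \code{n11}, \code{n10}, \code{n01}, \code{n00} (cell totals
#'   over sites), \code{nSites}, and \code{c}.
#' @export
estimateAdjacentOdds <- function(counts, sites) {
  d <- countsTable(counts)
  d <- d[d$pattern != "INDEL", , drop = FALSE]
  cells <- new.env(parent = emptyenv())
  for (id in unique(d$site_id)) {
    sp <- substratePositions(sites, id)
    if (length(sp) < 2L) next
    ds <- d[d$site_id == id, , drop = FALSE]
    posList <- patternPositions(ds$pattern)
    for (i in seq_len(length(sp) - 1L)) {
      a <- sp[i]; b <- sp[i + 1L]
      key <- paste0(a, "-", b)
      hasA <- vapply(posList, function(q) a %in% q, logical(1))
      hasB <- vapply(posList, function(q) b %in% q, logical(1))
      n11 <- sum(ds$count[hasA & hasB])
      n10 <- sum(ds$count[hasA & !hasB])
      n01 <- sum(ds$count[!hasA & hasB])
      n00 <- sum(ds$count[!hasA & !hasB])
      N <- n11 + n10 + n01 + n00
      if (N == 0) next
      add <- c(n11 = n11, n10 = n10, n01 = n01, n00 = n00,
               mhNum = n11 * n00 / N, mhDen = n10 * n01 / N, nSites = 1)
      prev <- if (!is.null(cells[[key]])) cells[[key]] else add * 0
      cells[[key]] <- prev + add
    }
  }
  keys <- ls(cells)
  if (!length(keys))
    return(data.frame(posA = integer(0), posB = integer(0),
                      n11 = numeric(0), n10 = numeric(0),
                      n01 = numeric(0), n00 = numeric(0),
                      nSites = integer(0), c = numeric(0)))
  out <- do.call(rbind, lapply(keys, function(k) {
    v <- cells[[k]]
    ab <- as.integer(strsplit(k, "-", fixed = TRUE)[[1]])
    if (v[["mhDen"]] <= 0)
      stop("zero discordant mass for pair ", k,
           "; apply add-one smoothing upstream", call. = FALSE)
    cEst <- v[["mhNum"]] / v[["mhDen"]]
    capped <- min(max(cEst, 1e-4), 1e4)
    if (capped != cEst)
      message("estimateAdjacentOdds: c for pair ", k, " capped")
    data.frame(posA = ab[1], posB = ab[2], n11 = v[["n11"]],
               n10 = v[["n10"]], n01 = v[["n01"]], n00 = v[["n00"]],
               nSites = as.integer(v[["nSites"]]), c = capped)
  }))
  out <- out[order(out$posA, out$posB), ]
  # global common odds ratio (all strata, all pairs): fallback for
  # position pairs absent from the training table
  gNum <- sum(vapply(keys, function(k) cells[[k]][["mhNum"]], numeric(1)))
  gDen <- sum(vapply(keys, function(k) cells[[k]][["mhDen"]], numeric(1)))
  attr(out, "globalC") <- if (gDen > 0) min(max(gNum / gDen, 1e-4), 1e4)
    else 1
  out
}

#' Per-site chain model from predicted marginals and pooled odds ratios
#'
#' Positions whose marginal is missing (non-C positions) are excluded from
#' the chain rather than fixed at zero. Adjacent substrate pairs look up
#' their pooled odds ratio by absolute position pair; pairs unseen in
#' training fall back to \code{defaultOdds}.
#'
#' @param site a one-site \linkS4class{TargetSiteSet} slice.
#' @param marginals data.frame \code{site_id}, \code{position},
#'   \code{efficiency} (e.g. from \code{\link{predictEfficiency}}).
#' @param oddsTable data.frame from \code{\link{estimateAdjacentOdds}}.
#' @param defaultOdds odds ratio used for pairs absent from
#'   \code{oddsTable}; \code{NULL} (default) uses the table's global
#'   pooled estimate when available, else 1 (independence).
#' @return a \linkS4class{ChainModel}, or \code{NULL} for sites with no
#'   substrate C.
#' @export
siteChain <- function(site, marginals, oddsTable = NULL,
                      defaultOdds = NULL) {
  if (is.null(defaultOdds)) {
    defaultOdds <- attr(oddsTable, "globalC")
    if (is.null(defaultOdds)) defaultOdds <- 1
  }
  s <- siteTable(site)
  if (nrow(s) != 1L) stop("siteChain needs exactly one site")
  sp <- substratePositions(site)
  if (!length(sp)) return(NULL)
  mg <- marginals[marginals$site_id == s$site_id &
                    marginals$position %in% sp, , drop = FALSE]
  mg <- mg[!is.na(mg$efficiency), , drop = FALSE]
  mg <- mg[order(mg$position), , drop = FALSE]
  if (!nrow(mg)) return(NULL)
  pos <- mg$position
  odds <- numeric(max(0L, nrow(mg) - 1L))
  if (length(odds)) for (i in seq_along(odds)) {
    o <- defaultOdds
    if (!is.null(oddsTable)) {
      hit <- oddsTable$posA == pos[i] & oddsTable$posB == pos[i + 1L]
      if (any(hit)) o <- oddsTable$c[hit][1]
    }
    odds[i] <- o
  }
  buildChain(pmin(pmax(mg$efficiency, 1e-9), 1 - 1e-9), odds, pos)
}
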