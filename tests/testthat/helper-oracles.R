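# Independent reference implementations used as oracles. These deliberately
# take different numerical routes than the package (grid/root search instead
# of the closed form, backward pairwise-product factorization instead of the
# forward conditional chain, textbook formulas for metrics).

# 2x2 joint with given margins and odds ratio, found by bracketed root
# search on log c (no closed form)
oracleJoint <- function(pA, pB, cc) {
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  f <- function(x) {
    p10 <- pA - x; p01 <- pB - x; p00 <- 1 - pA - pB + x
    log(cc) - (log(x) + log(p00) - log(p10) - log(p01))
  }
  eps <- (hi - lo) * 1e-13
  x <- uniroot(f, c(lo + eps, hi - eps), tol = 1e-15)$root
  c(p11 = x, p10 = pA - x, p01 = pB - x, p00 = 1 - pA - pB + x)
}

# joint over all binary patterns of a first-order chain, via the pairwise
# product form prod_i J_i(x_i, x_{i+1}) / prod_{i=2..n-1} p_i(x_i)
oracleChainProbs <- function(marginals, odds) {
  n <- length(marginals)
  grid <- as.matrix(expand.grid(rep(list(0:1), n)))
  joints <- if (n > 1L) lapply(seq_len(n - 1L), function(i)
    oracleJoint(marginals[i], marginals[i + 1L], odds[i])) else list()
  probs <- apply(grid, 1L, function(x) {
    if (n == 1L) return(ifelse(x[1] == 1L, marginals[1], 1 - marginals[1]))
    lp <- 0
    for (i in seq_len(n - 1L)) {
      J <- joints[[i]]
      # joints are named p11/p10/p01/p00, first index = left position
      cell <- paste0("p", x[i], x[i + 1L])
      lp <- lp + log(J[[cell]])
    }
    for (i in seq(2L, length.out = max(0L, n - 2L))) {
      pi <- if (x[i] == 1L) marginals[i] else 1 - marginals[i]
      lp <- lp - log(pi)
    }
    exp(lp)
  })
  names(probs) <- apply(grid, 1L, function(x)
    cgbesmart::makePattern(which(x == 1L)))
  probs
}

# textbook Pearson correlation and root mean square error
oraclePearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
oracleRMSE <- function(x, y) sqrt(sum((x - y)^2) / length(x))

# coarse grid + local refinement fit of the two-sided A/T context model
# (boost at -1, boost at +1, intercept) by cross-entropy; independent of
# the package's IRLS
oracleMotifGrid <- function(leftAT, rightAT, y) {
  nll <- function(par) {
    eta <- par[1] + par[2] * leftAT + par[3] * rightAT
    mu <- 1 / (1 + exp(-eta))
    -sum(y * log(mu) + (1 - y) * log(1 - mu))
  }
  best <- NULL; bestv <- Inf
  for (b0 in seq(-2, 0, by = 0.25))
    for (b1 in seq(0, 1.6, by = 0.2))
      for (b2 in seq(0, 1.6, by = 0.2)) {
        v <- nll(c(b0, b1, b2))
        if (v < bestv) { bestv <- v; best <- c(b0, b1, b2) }
      }
  optim(best, nll, method = "Nelder-Mead",
        control = list(reltol = 1e-12, maxit = 5000))$par
}
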