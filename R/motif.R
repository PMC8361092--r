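# Sequence-context (motif) model: ridge-stabilized logistic regression of
# fractional C-to-G efficiencies on one-hot context features around a
# targeted C.

#' One-hot encode the context around a targeted C
#'
#' Builds the binary feature vector over relative positions -k..-1, +1..+k
#' around a targeted C at protospacer position 4-7; the center position is
#' always C and carries no feature. Ordering is position-major with
#' nucleotides A < C < G < T, so the vector has length 8k with exactly one
#' hot bit per relative position.
#'
#' @param site a one-site \linkS4class{TargetSiteSet} slice.
#' @param cPosition protospacer position of the targeted C (4-7).
#' @param k context radius.
#' @return named numeric 0/1 vector of length 8k.
#' @export
encodeContext <- function(site, cPosition, k = 3L) {
  if (!cPosition %in% 4:7)
    stop("cPosition must lie in the editing window 4-7", call. = FALSE)
  s <- siteTable(site)
  if (nrow(s) != 1L) stop("encodeContext needs exactly one site")
  center <- s$protospacer_start + cPosition - 1L
  if (center - k < 1L || center + k > nchar(s$sequence))
    stop("insufficient flank for context radius k = ", k, call. = FALSE)
  ctx <- substr(s$sequence, center - k, center + k)
  chars <- strsplit(ctx, "", fixed = TRUE)[[1]]
  if (any(!chars %in% BASES))
    stop("ambiguity code in context", call. = FALSE)
  if (chars[k + 1L] != "C")
    stop("position ", cPosition, " is not a C in site ", s$site_id,
         call. = FALSE)
  rel <- c(-k:-1, 1:k)
  v <- numeric(8L * k)
  names(v) <- paste0(rep(ifelse(rel > 0, paste0("+", rel), rel),
                         each = 4L), ".", BASES)
  obs <- chars[-(k + 1L)]
  v[paste0(ifelse(rel > 0, paste0("+", rel), rel), ".", obs)] <- 1
  v
}

#' Feature matrix and labels for motif fitting
#'
#' Encodes every labeled (site, position) pair whose targeted C lies in the
#' editing window 4-7.
#'
#' @param sites a \linkS4class{TargetSiteSet}.
#' @param labels data.frame with \code{site_id}, \code{position},
#'   \code{efficiency} (see \code{\link{assembleTrainingTable}}).
#' @param k context radius.
#' @return list with \code{X} (n x 8k matrix), \code{y} (efficiencies),
#'   \code{site_id}, \code{position}.
#' @export
motifFeatures <- function(sites, labels, k = 3L) {
  lab <- labels[labels$position %in% 4:7, , drop = FALSE]
  if (!nrow(lab)) stop("no labels in the editing window 4-7")
  X <- t(vapply(seq_len(nrow(lab)), function(i)
    encodeContext(sites[lab$site_id[i]], lab$position[i], k),
    numeric(8L * k)))
  list(X = X, y = lab$efficiency, site_id = lab$site_id,
       position = lab$position)
}

#' Fit the logistic motif model
#'
#' Maximizes the fractional-response (quasi-binomial) log-likelihood --
#' cross-entropy with labels in [0,1] -- by iteratively reweighted least
#' squares with a small L2 ridge on the weights (not the intercept) for
#' numerical stability on separable data. The problem is convex, so the
#' fit is deterministic and invariant to row order.
#'
#' @param features n x 8k one-hot matrix (from \code{\link{motifFeatures}}
#'   or \code{\link{encodeContext}} rows).
#' @param labels efficiencies in [0,1], length n.
#' @param k context radius implied by the features.
#' @param ridge L2 penalty (default 1e-6).
#' @param maxit,tol IRLS iteration cap and gradient-norm tolerance.
#' @return a fitted \linkS4class{MotifModel}.
#' @export
fitMotifModel <- function(features, labels, k = ncol(features) %/% 8L,
                          ridge = 1e-6, maxit = 200L, tol = 1e-8) {
  X <- as.matrix(features)
  y <- as.numeric(labels)
  if (any(!is.finite(y)) || any(y < 0) || any(y > 1))
    stop("labels must be finite and in [0,1]", call. = FALSE)
  if (nrow(X) < ncol(X) + 1L)
    stop("need at least 8k+1 examples", call. = FALSE)
  Xi <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xi)
  pen <- c(0, rep(ridge, p - 1L))
  beta <- numeric(p)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxit)) {
    eta <- drop(Xi %*% beta)
    mu <- .sigmoid(eta)
    g <- drop(crossprod(Xi, y - mu)) - pen * beta
    if (sqrt(sum(g^2)) <= tol) { converged <- TRUE; break }
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Xi * w, Xi)
    diag(H) <- diag(H) + pen
    beta <- beta + solve(H, g)
  }
  W <- matrix(beta[-1], ncol = 4L, byrow = TRUE)
  rel <- c(-k:-1, 1:k)
  dimnames(W) <- list(ifelse(rel > 0, paste0("+", rel), as.character(rel)),
                      BASES)
  new("MotifModel", k = as.integer(k), weights = W, intercept = beta[1],
      fitted = TRUE, converged = converged, niter = it)
}

#' Predict efficiencies from a motif model
#'
#' @param model a fitted \linkS4class{MotifModel}.
#' @param features one-hot matrix with 8k columns in encoder order.
#' @return numeric vector of predicted efficiencies in (0,1).
#' @export
predictMotif <- function(model, features) {
  stopifnot(is(model, "MotifModel"))
  if (!model@fitted) stop("motif model is not fitted", call. = FALSE)
  beta <- c(model@intercept, as.vector(t(model@weights)))
  .sigmoid(drop(cbind(1, as.matrix(features)) %*% beta))
}

#' Mean-centered weight matrix for sequence-logo rendering
#'
#' Per relative position, the four nucleotide weights are centered to mean
#' zero (a per-position constant is not identified by one-hot features and
#' belongs to the intercept); positive cells mark preferred bases.
#'
#' @param model a fitted \linkS4class{MotifModel}.
#' @return 2k x 4 matrix (relative position x nucleotide).
#' @export
weightsToLogoMatrix <- function(model) {
  stopifnot(is(model, "MotifModel"))
  if (!model@fitted) stop("motif model is not fitted", call. = FALSE)
  sweep(model@weights, 1L, rowMeans(model@weights))
}

#' Write a logo matrix as TSV consumable by logo renderers
#'
#' @param model a fitted \linkS4class{MotifModel}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeLogoMatrix <- function(model, path) {
  m <- weightsToLogoMatrix(model)
  d <- data.frame(rel_position = rownames(m), m, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
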