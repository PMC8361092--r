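# Window-ensemble efficiency model: per protospacer position, nine
# feed-forward base models (window sizes 7/9/11, three seeds each) over a
# shared learned nucleotide embedding, combined by softmax-normalized
# learned weights. Trained by minibatch Adam on the MSE between observed
# and predicted efficiencies; the checkpoint with the best validation
# Pearson R is returned. All dense algebra is plain double-precision
# matrix arithmetic (BLAS), so training is bitwise reproducible for a
# fixed seed on a given platform.

#' Default training configuration for the efficiency ensemble
#'
#' @param seed integer seed governing initialization, shuffling and
#'   dropout.
#' @param embeddingDim embedding vector length per symbol (A/C/G/T/PAD).
#' @param windows odd window sizes of the base models.
#' @param replicatesPerWindow independently initialized replicates per
#'   window size.
#' @param hidden hidden-layer widths of each base model.
#' @param dropout dropout rate applied to hidden activations in training.
#' @param lr Adam learning rate.
#' @param batchSize minibatch size.
#' @param epochs maximum number of epochs.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param positions protospacer positions to build ensembles for.
#' @return named list of hyperparameters.
#' @export
efficiencyConfig <- function(seed = 1L, embeddingDim = 16L,
                             windows = c(7L, 9L, 11L),
                             replicatesPerWindow = 3L,
                             hidden = c(256L, 128L), dropout = 0.3,
                             lr = 1e-3, batchSize = 256L, epochs = 100L,
                             patience = 10L, positions = 1:20) {
  if (any(windows %% 2L == 0L)) stop("window sizes must be odd")
  list(seed = as.integer(seed), embeddingDim = as.integer(embeddingDim),
       windows = as.integer(windows),
       replicatesPerWindow = as.integer(replicatesPerWindow),
       hidden = as.integer(hidden), dropout = dropout, lr = lr,
       batchSize = as.integer(batchSize), epochs = as.integer(epochs),
       patience = as.integer(patience), positions = as.integer(positions))
}

#' Extract the symbol window centered on a protospacer position
#'
#' The window is drawn from the full stored sequence (flanks and PAM
#' included); positions beyond the available sequence are filled with the
#' dedicated \code{"PAD"} symbol.
#'
#' @param site a one-site \linkS4class{TargetSiteSet} slice.
#' @param position protospacer position (1-20).
#' @param w odd window size.
#' @return character vector of length \code{w} over A/C/G/T/PAD.
#' @export
extractWindow <- function(site, position, w) {
  if (w %% 2L == 0L) stop("window size must be odd", call. = FALSE)
  if (!position %in% 1:20) stop("position must lie in 1-20", call. = FALSE)
  s <- siteTable(site)
  if (nrow(s) != 1L) stop("extractWindow needs exactly one site")
  center <- s$protospacer_start + position - 1L
  idx <- center + seq.int(-(w - 1L) %/% 2L, (w - 1L) %/% 2L)
  chars <- strsplit(s$sequence, "", fixed = TRUE)[[1]]
  out <- rep("PAD", w)
  ok <- idx >= 1L & idx <= length(chars)
  out[ok] <- chars[idx[ok]]
  out
}

# integer symbol codes (A=1 C=2 G=3 T=4 PAD=5) for one site's sequence
.siteCodes <- function(sequence) {
  m <- match(strsplit(sequence, "", fixed = TRUE)[[1]], BASES)
  m  # validated upstream: no NA
}

# B x w matrix of symbol codes for a window around `position`, one row per
# site; out-of-range positions get the PAD code 5
.windowCodeMatrix <- function(codesList, starts, position, w) {
  half <- (w - 1L) %/% 2L
  B <- length(codesList)
  idx <- matrix(5L, nrow = B, ncol = w)
  off <- seq.int(-half, half)
  for (i in seq_len(B)) {
    j <- starts[i] + position - 1L + off
    ok <- j >= 1L & j <= length(codesList[[i]])
    idx[i, ok] <- codesList[[i]][j[ok]]
  }
  idx
}

# B x (w*d) input matrix: concatenated embedding rows per example
.gatherX <- function(E, idx) {
  B <- nrow(idx)
  tmp <- E[as.vector(t(idx)), , drop = FALSE]
  matrix(t(tmp), nrow = B, byrow = TRUE)
}

# scatter-add the input gradient back onto the embedding table
.scatterE <- function(dX, idx, nsym, d) {
  dtmp <- matrix(t(dX), ncol = d, byrow = TRUE)
  g <- as.vector(t(idx))
  rs <- rowsum(dtmp, group = g)
  dE <- matrix(0, nsym, d)
  dE[as.integer(rownames(rs)), ] <- rs
  dE
}

.initBranch <- function(d, hidden) {
  h1 <- hidden[1]; h2 <- hidden[2]
  list(W1 = matrix(rnorm(d * h1, sd = sqrt(2 / d)), d, h1),
       b1 = numeric(h1),
       W2 = matrix(rnorm(h1 * h2, sd = sqrt(2 / h1)), h1, h2),
       b2 = numeric(h2),
       W3 = matrix(rnorm(h2, sd = sqrt(1 / h2)), h2, 1),
       b3 = 0)
}

.zerosLike <- function(br) lapply(br, function(p) p * 0)

# forward pass for one base model; returns activations needed by backward
.branchForward <- function(X, br, dropout = 0) {
  B <- nrow(X)
  Z1 <- X %*% br$W1 + rep(br$b1, each = B)
  A1 <- Z1 * (Z1 > 0)
  M1 <- NULL
  if (dropout > 0) {
    M1 <- matrix((runif(length(A1)) >= dropout) / (1 - dropout), B)
    A1 <- A1 * M1
  }
  Z2 <- A1 %*% br$W2 + rep(br$b2, each = B)
  A2 <- Z2 * (Z2 > 0)
  M2 <- NULL
  if (dropout > 0) {
    M2 <- matrix((runif(length(A2)) >= dropout) / (1 - dropout), B)
    A2 <- A2 * M2
  }
  s <- .sigmoid(drop(A2 %*% br$W3) + br$b3)
  list(X = X, Z1 = Z1, A1 = A1, M1 = M1, Z2 = Z2, A2 = A2, M2 = M2, s = s)
}

# gradients of the loss wrt one base model's parameters and its input
.branchBackward <- function(fw, br, ds) {
  dz3 <- ds * fw$s * (1 - fw$s)
  dW3 <- crossprod(fw$A2, dz3)
  db3 <- sum(dz3)
  dA2 <- dz3 %*% t(br$W3)
  if (!is.null(fw$M2)) dA2 <- dA2 * fw$M2
  dZ2 <- dA2 * (fw$Z2 > 0)
  dW2 <- crossprod(fw$A1, dZ2)
  db2 <- colSums(dZ2)
  dA1 <- dZ2 %*% t(br$W2)
  if (!is.null(fw$M1)) dA1 <- dA1 * fw$M1
  dZ1 <- dA1 * (fw$Z1 > 0)
  dW1 <- crossprod(fw$X, dZ1)
  db1 <- colSums(dZ1)
  dX <- dZ1 %*% t(br$W1)
  list(grad = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3,
                   b3 = db3),
       dX = dX)
}

.adamStep <- function(p, g, st, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$m <- b1 * st$m + (1 - b1) * g
  st$v <- b2 * st$v + (1 - b2) * g * g
  p <- p - lr * (st$m / (1 - b1^t)) / (sqrt(st$v / (1 - b2^t)) + eps)
  list(p = p, st = st)
}

.softmax <- function(a) { e <- exp(a - max(a)); e / sum(e) }

#' Train the window-ensemble efficiency model
#'
#' Minimizes the mean square error between observed and predicted
#' efficiencies over (site, substrate-C position) pairs with minibatch
#' Adam; dropout is active in training only. After every epoch the pooled
#' Pearson R on the validation set is recorded and the parameters of the
#' best validation epoch are kept as the returned checkpoint. Training is
#' fully reproducible given \code{config$seed}.
#'
#' @param sites a \linkS4class{TargetSiteSet} covering all ids in
#'   \code{trainIds} and \code{valIds}.
#' @param labels data.frame with \code{site_id}, \code{position},
#'   \code{efficiency} (labels must sit on reference-C positions only).
#' @param trainIds,valIds disjoint site-id vectors; \code{valIds} must be
#'   nonempty.
#' @param config list from \code{\link{efficiencyConfig}}.
#' @param verbose print per-epoch progress.
#' @return an \linkS4class{EfficiencyEnsemble}.
#' @export
trainEfficiencyModel <- function(sites, labels, trainIds, valIds,
                                 config = efficiencyConfig(),
                                 verbose = FALSE) {
  if (length(valIds) == 0L) stop("validation set is empty", call. = FALSE)
  if (length(intersect(trainIds, valIds)))
    stop("train and validation sets must be disjoint by site",
         call. = FALSE)
  st <- siteTable(sites)
  if (any(!is.finite(labels$efficiency)) || any(labels$efficiency < 0) ||
      any(labels$efficiency > 1))
    stop("labels must lie in [0,1]", call. = FALSE)

  # labels must index reference Cs
  protoOf <- setNames(substr(st$sequence, st$protospacer_start,
                             st$protospacer_start + 19L), st$site_id)
  isC <- substr(protoOf[labels$site_id], labels$position,
                labels$position) == "C"
  if (!all(isC))
    stop("labels present at non-C protospacer positions (e.g. site ",
         labels$site_id[!isC][1], " position ",
         labels$position[!isC][1], ")", call. = FALSE)

  codes <- lapply(st$sequence, .siteCodes)
  names(codes) <- st$site_id
  starts <- setNames(st$protospacer_start, st$site_id)

  wvec <- rep(config$windows, each = config$replicatesPerWindow)
  nb <- length(wvec)
  d <- config$embeddingDim

  prep <- function(ids) {
    lab <- labels[labels$site_id %in% ids, , drop = FALSE]
    out <- list()
    for (p in config$positions) {
      lp <- lab[lab$position == p, , drop = FALSE]
      if (!nrow(lp)) next
      cl <- codes[lp$site_id]
      sx <- starts[lp$site_id]
      idx <- lapply(unique(config$windows), function(w)
        .windowCodeMatrix(cl, sx, p, w))
      names(idx) <- as.character(unique(config$windows))
      out[[as.character(p)]] <- list(y = lp$efficiency,
                                     site_id = lp$site_id, idx = idx)
    }
    out
  }

  set.seed(config$seed)
  trainData <- prep(trainIds)
  valData <- prep(valIds)
  if (!length(trainData)) stop("no training labels", call. = FALSE)
  if (!length(valData)) stop("no validation labels", call. = FALSE)

  E <- matrix(rnorm(5L * d, sd = 0.1), 5L, d,
              dimnames = list(SYMBOLS, NULL))
  eSt <- list(m = E * 0, v = E * 0)
  posParams <- list()
  posState <- list()
  for (p in names(trainData)) {
    branches <- lapply(seq_len(nb), function(m)
      .initBranch(wvec[m] * d, config$hidden))
    posParams[[p]] <- list(branches = branches, alpha = numeric(nb))
    posState[[p]] <- list(branches = lapply(branches, .zerosLike),
                          branches_v = lapply(branches, .zerosLike),
                          alpha = list(m = numeric(nb), v = numeric(nb)))
  }

  predictSet <- function(data) {
    pred <- numeric(0); obs <- numeric(0)
    for (p in names(data)) {
      pp <- posParams[[p]]
      if (is.null(pp)) next
      wts <- .softmax(pp$alpha)
      yh <- 0
      for (m in seq_len(nb)) {
        X <- .gatherX(E, data[[p]]$idx[[as.character(wvec[m])]])
        yh <- yh + wts[m] * .branchForward(X, pp$branches[[m]])$s
      }
      pred <- c(pred, yh); obs <- c(obs, data[[p]]$y)
    }
    list(pred = pred, obs = obs)
  }

  step <- 0L
  best <- NULL; bestScore <- -Inf; bestEpoch <- 0L; wait <- 0L
  hist <- data.frame(epoch = integer(0), val_r = numeric(0),
                     val_mse = numeric(0))

  for (epoch in seq_len(config$epochs)) {
    for (p in names(trainData)) {
      dat <- trainData[[p]]
      n <- length(dat$y)
      perm <- sample.int(n)
      starts_b <- seq(1L, n, by = config$batchSize)
      for (b0 in starts_b) {
        rows <- perm[b0:min(b0 + config$batchSize - 1L, n)]
        B <- length(rows)
        y <- dat$y[rows]
        pp <- posParams[[p]]
        ps <- posState[[p]]
        wts <- .softmax(pp$alpha)
        fws <- vector("list", nb)
        Xs <- vector("list", nb)
        svals <- matrix(0, B, nb)
        for (m in seq_len(nb)) {
          idx <- dat$idx[[as.character(wvec[m])]][rows, , drop = FALSE]
          Xs[[m]] <- idx
          fws[[m]] <- .branchForward(.gatherX(E, idx), pp$branches[[m]],
                                     config$dropout)
          svals[, m] <- fws[[m]]$s
        }
        yhat <- drop(svals %*% wts)
        dyhat <- 2 * (yhat - y) / B
        step <- step + 1L
        dE <- matrix(0, 5L, d)
        for (m in seq_len(nb)) {
          bk <- .branchBackward(fws[[m]], pp$branches[[m]],
                                dyhat * wts[m])
          dE <- dE + .scatterE(bk$dX, Xs[[m]], 5L, d)
          br <- pp$branches[[m]]
          for (nm in names(br)) {
            up <- .adamStep(br[[nm]], bk$grad[[nm]],
                            list(m = ps$branches[[m]][[nm]],
                                 v = ps$branches_v[[m]][[nm]]),
                            config$lr, step)
            br[[nm]] <- up$p
            ps$branches[[m]][[nm]] <- up$st$m
            ps$branches_v[[m]][[nm]] <- up$st$v
          }
          pp$branches[[m]] <- br
        }
        dalpha <- drop(crossprod(svals - yhat, dyhat)) * wts
        upA <- .adamStep(pp$alpha, dalpha, ps$alpha, config$lr, step)
        pp$alpha <- upA$p; ps$alpha <- upA$st
        upE <- .adamStep(E, dE, eSt, config$lr, step)
        E <- upE$p; eSt <- upE$st
        posParams[[p]] <- pp
        posState[[p]] <- ps
      }
    }
    v <- predictSet(valData)
    r <- .pearson(v$pred, v$obs)
    mse <- mean((v$pred - v$obs)^2)
    score <- if (is.na(r)) -1 - mse else r
    hist <- rbind(hist, data.frame(epoch = epoch, val_r = r,
                                   val_mse = mse))
    if (verbose)
      message(sprintf("epoch %3d  val R %.4f  val MSE %.5f", epoch,
                      if (is.na(r)) NA_real_ else r, mse))
    if (score > bestScore + 1e-12) {
      bestScore <- score; bestEpoch <- epoch; wait <- 0L
      best <- list(E = E, positions = posParams)
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }

  new("EfficiencyEnsemble", embedding = best$E, positions = best$positions,
      config = config, history = hist, bestEpoch = bestEpoch)
}

#' Predict per-position C-to-G efficiencies for target sites
#'
#' Runs the stored checkpoint in evaluation mode (no dropout), so repeated
#' calls are deterministic. Positions without a reference C (or without a
#' trained ensemble) carry \code{NA}.
#'
#' @param model an \linkS4class{EfficiencyEnsemble}.
#' @param sites a \linkS4class{TargetSiteSet}.
#' @return data.frame with columns \code{site_id}, \code{position} (1-20),
#'   \code{efficiency}.
#' @export
predictEfficiency <- function(model, sites) {
  stopifnot(is(model, "EfficiencyEnsemble"))
  st <- siteTable(sites)
  codes <- lapply(st$sequence, .siteCodes)
  starts <- st$protospacer_start
  proto <- substr(st$sequence, starts, starts + 19L)
  cfg <- model@config
  wvec <- rep(cfg$windows, each = cfg$replicatesPerWindow)
  nb <- length(wvec)
  out <- expand.grid(site_id = st$site_id, position = 1:20,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$efficiency <- NA_real_
  for (p in 1:20) {
    pp <- model@positions[[as.character(p)]]
    if (is.null(pp)) next
    hasC <- substr(proto, p, p) == "C"
    if (!any(hasC)) next
    sel <- which(hasC)
    wts <- .softmax(pp$alpha)
    yh <- 0
    for (m in seq_len(nb)) {
      idx <- .windowCodeMatrix(codes[sel], starts[sel], p, wvec[m])
      yh <- yh + wts[m] *
        .branchForward(.gatherX(model@embedding, idx),
                       pp$branches[[m]])$s
    }
    rowsP <- which(out$position == p)  # aligned with st row order
    out$efficiency[rowsP[sel]] <- yh
  }
  out[order(out$site_id, out$position), ]
}
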