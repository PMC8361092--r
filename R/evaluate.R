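# Dataset splitting and benchmarking metrics: seeded 6:1:3 and 4:1 splits
# by site, trisection cross-validation with a 10% validation hold-out,
# and Pearson R / RMSE in pooled or per-position-averaged mode.

#' Split sites into train / validation / test by fixed proportions
#'
#' Seeded shuffle followed by largest-remainder rounding of the requested
#' fractions, so 100 sites under the default 6:1:3 give exactly 60/10/30.
#' Splitting is always by site, never by position.
#'
#' @param siteIds character vector of site ids (>= 10).
#' @param seed integer seed.
#' @param fractions named numeric vector \code{train}, \code{val},
#'   \code{test} summing to 1.
#' @return list with character vectors \code{train}, \code{val},
#'   \code{test} forming a partition of \code{siteIds}.
#' @export
split613 <- function(siteIds, seed = 1L,
                     fractions = c(train = 0.6, val = 0.1, test = 0.3)) {
  n <- length(siteIds)
  if (n < 10L) stop("need at least 10 sites", call. = FALSE)
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  sizes <- floor(fractions * n)
  rem <- fractions * n - sizes
  short <- n - sum(sizes)
  if (short > 0L) {
    o <- order(rem, decreasing = TRUE)
    sizes[o[seq_len(short)]] <- sizes[o[seq_len(short)]] + 1L
  }
  ids <- .withSeed(seed, sample(siteIds))
  ends <- cumsum(sizes)
  list(train = ids[seq_len(sizes[1])],
       val = if (sizes[2] > 0L) ids[(ends[1] + 1L):ends[2]] else
         character(0),
       test = if (sizes[3] > 0L) ids[(ends[2] + 1L):ends[3]] else
         character(0))
}

#' 4:1 train/validation split (no test portion)
#'
#' Preset of \code{\link{split613}} used when a model trained on library
#' data is evaluated on external (endogenous) sites.
#'
#' @inheritParams split613
#' @return list with \code{train}, \code{val}, empty \code{test}.
#' @export
split41 <- function(siteIds, seed = 1L) {
  split613(siteIds, seed, c(train = 0.8, val = 0.2, test = 0))
}

#' Trisection cross-validation plans
#'
#' Splits sites into three folds; each fold serves once as the test set
#' while the other two form the training portion, of which 10% is held
#' out for validation. Concatenated test sets cover every site exactly
#' once, so per-site predictions from the three folds can be merged into
#' one final result.
#'
#' @param siteIds character vector of site ids (>= 15).
#' @param seed integer seed.
#' @return list of three plans, each \code{list(train, val, test)}.
#' @export
trisectionCV <- function(siteIds, seed = 1L) {
  n <- length(siteIds)
  if (n < 15L) stop("need at least 15 sites", call. = FALSE)
  ids <- .withSeed(seed, sample(siteIds))
  fold <- rep(1:3, times = c(n %/% 3 + (n %% 3 >= 1),
                             n %/% 3 + (n %% 3 >= 2), n %/% 3))
  plans <- vector("list", 3L)
  for (k in 1:3) {
    test <- ids[fold == k]
    rest <- ids[fold != k]
    nVal <- max(1L, round(0.1 * length(rest)))
    val <- rest[seq_len(nVal)]          # rest is already shuffled
    plans[[k]] <- list(train = rest[-seq_len(nVal)], val = val,
                       test = test)
  }
  plans
}

#' Pearson R and RMSE between predicted and observed efficiencies
#'
#' \code{mode = "pooled"} computes a single Pearson correlation and RMSE
#' over all aligned (site, position) pairs; \code{mode =
#' "per_position_average"} computes a Pearson R per protospacer position
#' and reports their unweighted mean (positions with undefined variance
#' are skipped and counted). Rows with missing values in either input are
#' dropped.
#'
#' @param predicted,observed data.frames with columns \code{site_id},
#'   \code{position} and \code{efficiency}.
#' @param mode \code{"pooled"} or \code{"per_position_average"}.
#' @return list with elements \code{r}, \code{rmse} (pooled mode) or
#'   \code{r} (mean), \code{per_position} (named vector),
#'   \code{skipped} (count); plus \code{n}, the number of pairs used.
#' @export
benchmarkPredictions <- function(predicted, observed,
                                 mode = c("pooled",
                                          "per_position_average")) {
  mode <- match.arg(mode)
  m <- merge(predicted[, c("site_id", "position", "efficiency")],
             observed[, c("site_id", "position", "efficiency")],
             by = c("site_id", "position"),
             suffixes = c("_pred", "_obs"))
  m <- m[is.finite(m$efficiency_pred) & is.finite(m$efficiency_obs), ,
         drop = FALSE]
  if (nrow(m) == 0L) stop("no overlapping (site, position) pairs",
                          call. = FALSE)
  if (mode == "pooled") {
    if (nrow(m) < 3L) stop("need >= 3 pairs for a correlation",
                           call. = FALSE)
    list(r = .pearson(m$efficiency_pred, m$efficiency_obs),
         rmse = .rmse(m$efficiency_pred, m$efficiency_obs),
         n = nrow(m))
  } else {
    rs <- c(); skipped <- 0L
    for (p in sort(unique(m$position))) {
      mp <- m[m$position == p, , drop = FALSE]
      if (nrow(mp) < 3L) { skipped <- skipped + 1L; next }
      r <- .pearson(mp$efficiency_pred, mp$efficiency_obs)
      if (is.na(r)) { skipped <- skipped + 1L; next }
      rs[as.character(p)] <- r
    }
    if (!length(rs)) stop("no position with a defined correlation",
                          call. = FALSE)
    list(r = mean(rs), per_position = rs, skipped = skipped, n = nrow(m))
  }
}
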