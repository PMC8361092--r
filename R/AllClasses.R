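#' @import methods
NULL

# -- TargetSiteSet -----------------------------------------------------------

#' Set of guide/target sites
#'
#' Holds one row per target site: a site id, the amplicon sequence
#' (protospacer + PAM + flanks, always stored in the frame where the
#' protospacer reads 5'->3'), the 1-based offset of protospacer position 1
#' within the sequence, and the orientation in which raw reads of this site
#' are expected (\code{"forward"} or \code{"reverse"}). Protospacer
#' positions are numbered 1-20 from the PAM-distal end with the PAM at
#' positions 21-23. Every protospacer position must have at least 5 nt of
#' sequence on each side so that the widest prediction window (11 nt) never
#' runs out of context.
#'
#' @slot sites data.frame with columns \code{site_id}, \code{sequence},
#'   \code{protospacer_start}, \code{strand}.
#' @export
setClass("TargetSiteSet", representation(sites = "data.frame"))

.validTargetSiteSet <- function(object) {
  s <- object@sites
  need <- c("site_id", "sequence", "protospacer_start", "strand")
  if (!all(need %in% names(s)))
    return(paste("missing columns:", paste(setdiff(need, names(s)),
                                           collapse = ", ")))
  if (nrow(s) == 0L) return(TRUE)
  if (anyDuplicated(s$site_id)) return("duplicate site_id")
  msgs <- character(0)
  for (i in seq_len(nrow(s))) {
    id <- s$site_id[i]
    if (grepl("[^ACGT]", s$sequence[i])) {
      msgs <- c(msgs, paste0("site ", id, ": sequence contains non-ACGT"))
      next
    }
    st <- s$protospacer_start[i]
    n <- nchar(s$sequence[i])
    if (is.na(st) || st < 6L)
      msgs <- c(msgs, paste0("site ", id, ": fewer than 5 nt left flank"))
    else if (n < st + 24L)
      msgs <- c(msgs, paste0("site ", id,
                             ": fewer than 5 nt right of protospacer ",
                             "position 20 (PAM + flank too short)"))
    if (!s$strand[i] %in% c("forward", "reverse"))
      msgs <- c(msgs, paste0("site ", id, ": strand must be forward/reverse"))
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
}
setValidity("TargetSiteSet", .validTargetSiteSet)

#' Construct a TargetSiteSet
#'
#' @param site_id character vector of unique ids.
#' @param sequence A/C/G/T amplicon sequences (forward frame).
#' @param protospacer_start 1-based offset of protospacer position 1.
#' @param strand read orientation, \code{"forward"} or \code{"reverse"}.
#' @return a \linkS4class{TargetSiteSet}.
#' @export
TargetSiteSet <- function(site_id, sequence, protospacer_start,
                          strand = "forward") {
  df <- data.frame(site_id = as.character(site_id),
                   sequence = toupper(as.character(sequence)),
                   protospacer_start = as.integer(protospacer_start),
                   strand = rep_len(as.character(strand), length(site_id)),
                   stringsAsFactors = FALSE)
  new("TargetSiteSet", sites = df)
}

#' @describeIn TargetSiteSet number of sites
#' @param x a TargetSiteSet.
#' @export
setMethod("length", "TargetSiteSet", function(x) nrow(x@sites))

#' Site ids of a TargetSiteSet
#' @param x a TargetSiteSet.
#' @return character vector.
#' @export
siteIds <- function(x) x@sites$site_id

#' Site table of a TargetSiteSet as a data.frame
#' @param x a TargetSiteSet.
#' @return data.frame with one row per site.
#' @export
siteTable <- function(x) x@sites

#' @export
setMethod("[", "TargetSiteSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@sites$site_id)
  initialize(x, sites = x@sites[i, , drop = FALSE])
})

setMethod("show", "TargetSiteSet", function(object) {
  cat("TargetSiteSet with", nrow(object@sites), "sites\n")
  if (nrow(object@sites)) {
    n <- min(3L, nrow(object@sites))
    for (i in seq_len(n))
      cat("  ", object@sites$site_id[i], " ",
          object@sites$sequence[i], " [", object@sites$strand[i], "]\n",
          sep = "")
    if (nrow(object@sites) > n) cat("  ...\n")
  }
})

#' Protospacer (+PAM) subsequence of one site
#'
#' @param site one-row slice of a TargetSiteSet (or the set plus an id).
#' @param id site id when \code{site} holds several sites.
#' @param withPAM include PAM positions 21-23.
#' @return character scalar.
#' @export
protospacerSeq <- function(site, id = NULL, withPAM = FALSE) {
  s <- siteTable(site)
  if (!is.null(id)) s <- s[s$site_id == id, , drop = FALSE]
  if (nrow(s) != 1L) stop("need exactly one site")
  substr(s$sequence, s$protospacer_start,
         s$protospacer_start + if (withPAM) 22L else 19L)
}

#' Protospacer positions (1-20) holding a reference C
#'
#' @param site a one-site TargetSiteSet slice.
#' @param id optional site id.
#' @return sorted integer vector of substrate-C positions.
#' @export
substratePositions <- function(site, id = NULL) {
  proto <- protospacerSeq(site, id)
  which(strsplit(proto, "", fixed = TRUE)[[1]] == "C")
}

# -- OutcomeCounts -----------------------------------------------------------

#' Per-site read counts keyed by edit pattern
#'
#' Long-format table of read counts: one row per (site, replicate, pattern)
#' with patterns in canonical form (\code{"REF"}, \code{"INDEL"}, or sorted
#' C-to-G tokens like \code{"4G+7G"}).
#'
#' @slot counts data.frame with columns \code{site_id}, \code{replicate},
#'   \code{pattern}, \code{count}.
#' @export
setClass("OutcomeCounts", representation(counts = "data.frame"))

.validOutcomeCounts <- function(object) {
  d <- object@counts
  need <- c("site_id", "replicate", "pattern", "count")
  if (!all(need %in% names(d)))
    return(paste("missing columns:", paste(setdiff(need, names(d)),
                                           collapse = ", ")))
  if (nrow(d) == 0L) return(TRUE)
  if (any(!is.finite(d$count)) || any(d$count < 0))
    return("counts must be nonnegative")
  if (any(d$count != round(d$count))) return("counts must be integers")
  ok <- tryCatch({ canonicalPattern(d$pattern); TRUE },
                 error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) return(ok)
  if (any(canonicalPattern(d$pattern) != d$pattern))
    return("patterns not in canonical form")
  TRUE
}
setValidity("OutcomeCounts", .validOutcomeCounts)

#' Construct an OutcomeCounts table
#'
#' Pattern strings are canonicalized (positions sorted); rows with the same
#' (site, replicate, canonical pattern) are summed.
#'
#' @param site_id,replicate,pattern,count vectors of equal length.
#' @return an \linkS4class{OutcomeCounts}.
#' @export
OutcomeCounts <- function(site_id, replicate, pattern, count) {
  if (any(!is.finite(count)) || any(count < 0))
    stop("counts must be nonnegative", call. = FALSE)
  d <- data.frame(site_id = as.character(site_id),
                  replicate = as.character(replicate),
                  pattern = canonicalPattern(as.character(pattern)),
                  count = as.numeric(count), stringsAsFactors = FALSE)
  agg <- stats::aggregate(count ~ site_id + replicate + pattern, data = d,
                          FUN = sum)
  new("OutcomeCounts", counts = agg)
}

#' Counts table of an OutcomeCounts object
#' @param x an OutcomeCounts.
#' @return data.frame.
#' @export
countsTable <- function(x) x@counts

setMethod("show", "OutcomeCounts", function(object) {
  d <- object@counts
  cat("OutcomeCounts:", length(unique(d$site_id)), "sites,",
      length(unique(d$replicate)), "replicates,",
      sum(d$count), "reads\n")
})

# -- MotifModel --------------------------------------------------------------

#' Logistic-regression motif model
#'
#' Weights over one-hot context features around a targeted C: one weight
#' per (relative position in -k..-1, +1..+k) x (A, C, G, T) cell, plus an
#' intercept. The center position is always C and carries no feature.
#'
#' @slot k context radius (nt on each side of the targeted C).
#' @slot weights 2k x 4 matrix (rows named "-k".."-1","+1".."+k").
#' @slot intercept numeric scalar.
#' @slot fitted logical.
#' @slot converged logical; \code{niter} iterations used.
#' @slot niter integer.
#' @export
setClass("MotifModel", representation(k = "integer", weights = "matrix",
                                      intercept = "numeric",
                                      fitted = "logical",
                                      converged = "logical",
                                      niter = "integer"))

.validMotifModel <- function(object) {
  if (object@k < 1L) return("k must be >= 1")
  if (!identical(dim(object@weights), c(2L * object@k, 4L)))
    return("weights must be a 2k x 4 matrix")
  if (any(!is.finite(object@weights))) return("weights must be finite")
  TRUE
}
setValidity("MotifModel", .validMotifModel)

setMethod("show", "MotifModel", function(object) {
  cat("MotifModel: context radius k =", object@k,
      if (object@fitted) "(fitted)" else "(unfitted)", "\n")
  if (object@fitted) {
    cat("  intercept:", signif(object@intercept, 4), "\n")
    print(signif(object@weights, 3))
  }
})

# -- EfficiencyEnsemble ------------------------------------------------------

#' Window-ensemble efficiency model
#'
#' Per protospacer position, nine feed-forward base models (window sizes 7,
#' 9 and 11, three independently initialized replicates each) over a shared
#' learned nucleotide embedding, combined by softmax-normalized learned
#' weights into a single sigmoid-bounded C-to-G efficiency prediction.
#'
#' @slot embedding 5 x d matrix (rows A, C, G, T, PAD).
#' @slot positions list (one element per trained protospacer position) of
#'   lists with elements \code{branches} (nine parameter lists) and
#'   \code{alpha} (combination-weight logits).
#' @slot config list of training hyperparameters (seeded).
#' @slot history data.frame of per-epoch validation metrics.
#' @slot bestEpoch integer epoch whose checkpoint is stored.
#' @export
setClass("EfficiencyEnsemble", representation(embedding = "matrix",
                                              positions = "list",
                                              config = "list",
                                              history = "data.frame",
                                              bestEpoch = "integer"))

setMethod("show", "EfficiencyEnsemble", function(object) {
  cat("EfficiencyEnsemble:", length(object@positions),
      "position ensembles x", length(object@positions[[1]]$branches),
      "base models; embedding dim", ncol(object@embedding), "\n")
  cat("  best epoch:", object@bestEpoch, "of", nrow(object@history),
      "; validation R =",
      signif(max(object@history$val_r, na.rm = TRUE), 4), "\n")
})

#' Softmax-normalized combination weights of an ensemble
#'
#' @param model an \linkS4class{EfficiencyEnsemble}.
#' @return matrix (position x base model), rows summing to 1.
#' @export
combinationWeights <- function(model) {
  stopifnot(is(model, "EfficiencyEnsemble"))
  t(vapply(model@positions, function(p) {
    e <- exp(p$alpha - max(p$alpha)); e / sum(e)
  }, numeric(length(model@positions[[1]]$alpha))))
}

#' Training history of an ensemble
#' @param model an EfficiencyEnsemble.
#' @return data.frame with one row per epoch.
#' @export
trainingHistory <- function(model) model@history

# -- ChainModel --------------------------------------------------------------

#' Chain-factorized joint model over per-position edit indicators
#'
#' Orders the substrate-C positions of one site left to right, keeps the
#' per-position marginal editing probabilities, and links adjacent positions
#' through conditional tables derived from pairwise odds ratios so that the
#' forward-factorized joint p(X1) p(X2|X1) ... p(Xn|Xn-1) reproduces every
#' marginal exactly.
#'
#' @slot positions integer vector of protospacer positions (ascending).
#' @slot marginals numeric vector, same length, values in (0,1).
#' @slot odds numeric vector of adjacent-pair odds ratios (length n-1).
#' @slot conditionals list of 2x2 matrices; rows = previous state (0,1),
#'   columns = next state (0,1), each row summing to 1.
#' @export
setClass("ChainModel", representation(positions = "integer",
                                      marginals = "numeric",
                                      odds = "numeric",
                                      conditionals = "list"))

.validChainModel <- function(object) {
  n <- length(object@positions)
  if (n < 1L) return("need at least one position")
  if (length(object@marginals) != n) return("marginals length mismatch")
  if (any(object@marginals <= 0 | object@marginals >= 1))
    return("marginals must lie strictly in (0,1)")
  if (n > 1L) {
    if (length(object@odds) != n - 1L) return("odds length mismatch")
    if (any(object@odds <= 0)) return("odds ratios must be positive")
    if (length(object@conditionals) != n - 1L)
      return("conditionals length mismatch")
    for (m in object@conditionals) {
      if (!all(abs(rowSums(m) - 1) < 1e-9))
        return("conditional rows must sum to 1")
    }
  }
  if (is.unsorted(object@positions, strictly = TRUE))
    return("positions must be strictly increasing")
  TRUE
}
setValidity("ChainModel", .validChainModel)

setMethod("show", "ChainModel", function(object) {
  cat("ChainModel over positions",
      paste(object@positions, collapse = ", "), "\n")
  cat("  marginals:", paste(signif(object@marginals, 3), collapse = ", "),
      "\n")
  if (length(object@odds))
    cat("  adjacent odds ratios:",
        paste(signif(object@odds, 3), collapse = ", "), "\n")
})

#' Marginal editing probabilities of a ChainModel
#' @param x a ChainModel.
#' @return named numeric vector (names = protospacer positions).
#' @export
chainMarginals <- function(x) setNames(x@marginals, x@positions)

#' Adjacent-pair odds ratios of a ChainModel
#' @param x a ChainModel.
#' @return numeric vector of length n-1.
#' @export
chainOdds <- function(x) x@odds
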