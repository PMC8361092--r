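# Synthetic sgRNA-library simulator: emulates a paired guide/target
# oligonucleotide library (20-nt protospacer, NGG PAM at positions 21-23,
# flanking context) with motif-dependent C-to-G efficiencies peaking in
# the protospacer 4-7 editing window, negative-binomial coverage,
# indel reads, A/T bystander conversions and correlated co-editing of
# adjacent substrate Cs. The generator exports its ground truth so every
# recovery metric can be computed without re-running it.

#' Simulation configuration
#'
#' Defaults describe the library regime the models are built for: low
#' baseline C-to-G efficiency lifted inside the 4-7 editing window and by
#' A/T (W) neighbors on either side of the targeted C (the WCW motif
#' preference), ~1000x coverage with overdispersion, a 5% indel rate, a 2%
#' A/T bystander rate, and positively correlated co-editing of adjacent
#' substrate Cs (odds ratio 4).
#'
#' @param nSites number of sites.
#' @param seed mandatory integer seed.
#' @param baselineLogit baseline log-odds of C-to-G conversion.
#' @param positionEffect logit boost for protospacer positions 4-7.
#' @param motifMinusOneAT,motifPlusOneAT logit boost when the -1/+1
#'   neighbor of the targeted C is A or T.
#' @param coverageMean,coverageDispersion negative-binomial read-count law
#'   (mean and size).
#' @param indelRate per-read probability of an indel outcome.
#' @param bystanderRate per-read probability of one C-to-A/T conversion at
#'   an unedited substrate C.
#' @param adjacentOdds true odds ratio c between adjacent substrate Cs.
#' @param replicates number of experimental replicates.
#' @param reverseFraction fraction of sites whose reads are emitted in
#'   reverse orientation.
#' @param flank flanking nt on each side of protospacer + PAM.
#' @param pam PAM pattern; \code{"N"} positions drawn uniformly.
#' @return named list.
#' @export
simConfig <- function(nSites = 500L, seed = 1L, baselineLogit = -1,
                      positionEffect = 1, motifMinusOneAT = 0.8,
                      motifPlusOneAT = 0.8, coverageMean = 1000,
                      coverageDispersion = 10, indelRate = 0.05,
                      bystanderRate = 0.02, adjacentOdds = 4,
                      replicates = 2L, reverseFraction = 0,
                      flank = 10L, pam = "NGG") {
  if (nSites < 1L) stop("nSites must be >= 1", call. = FALSE)
  if (coverageMean < 1) stop("coverage mean must be >= 1", call. = FALSE)
  if (adjacentOdds <= 0) stop("adjacentOdds must be positive",
                              call. = FALSE)
  stopifnot(indelRate >= 0, indelRate <= 1, bystanderRate >= 0,
            bystanderRate <= 1, reverseFraction >= 0,
            reverseFraction <= 1, flank >= 5L)
  list(nSites = as.integer(nSites), seed = as.integer(seed),
       baselineLogit = baselineLogit, positionEffect = positionEffect,
       motifMinusOneAT = motifMinusOneAT, motifPlusOneAT = motifPlusOneAT,
       coverageMean = coverageMean,
       coverageDispersion = coverageDispersion, indelRate = indelRate,
       bystanderRate = bystanderRate, adjacentOdds = adjacentOdds,
       replicates = as.integer(replicates),
       reverseFraction = reverseFraction, flank = as.integer(flank),
       pam = pam)
}

#' Simulate a guide/target library with known per-position truth
#'
#' Draws uniform-random 20-nt protospacers with the configured PAM and
#' flanks, then computes the true conversion probability of every
#' substrate C as logistic(baseline + positionEffect * [pos in 4-7] +
#' motif terms for A/T neighbors). Deterministic given the seed.
#'
#' @param config list from \code{\link{simConfig}}.
#' @return list with \code{sites} (a \linkS4class{TargetSiteSet}) and
#'   \code{truth} (list: \code{efficiency} data.frame site_id, position,
#'   p_true; \code{adjacentOdds}; \code{indelRate};
#'   \code{bystanderRate}).
#' @export
simulateLibrary <- function(config = simConfig()) {
  set.seed(config$seed)
  n <- config$nSites
  fl <- config$flank
  pamChars <- strsplit(config$pam, "", fixed = TRUE)[[1]]
  ids <- sprintf("site%05d", seq_len(n))
  seqs <- character(n)
  for (i in seq_len(n)) {
    pam <- vapply(pamChars, function(ch)
      if (ch == "N") sample(BASES, 1L) else ch, character(1))
    seqs[i] <- paste0(paste(sample(BASES, fl, replace = TRUE),
                            collapse = ""),
                      paste(sample(BASES, 20L, replace = TRUE),
                            collapse = ""),
                      paste(pam, collapse = ""),
                      paste(sample(BASES, fl, replace = TRUE),
                            collapse = ""))
  }
  strand <- ifelse(runif(n) < config$reverseFraction, "reverse", "forward")
  sites <- TargetSiteSet(ids, seqs, rep(fl + 1L, n), strand)

  eff <- list()
  for (i in seq_len(n)) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    st <- fl + 1L
    cpos <- which(chars[st:(st + 19L)] == "C")
    if (!length(cpos)) next
    center <- st + cpos - 1L
    logit <- config$baselineLogit +
      config$positionEffect * (cpos %in% 4:7) +
      config$motifMinusOneAT * (chars[center - 1L] %in% c("A", "T")) +
      config$motifPlusOneAT * (chars[center + 1L] %in% c("A", "T"))
    eff[[length(eff) + 1L]] <-
      data.frame(site_id = ids[i], position = cpos,
                 p_true = .sigmoid(logit), stringsAsFactors = FALSE)
  }
  list(sites = sites,
       truth = list(efficiency = do.call(rbind, eff),
                    adjacentOdds = config$adjacentOdds,
                    indelRate = config$indelRate,
                    bystanderRate = config$bystanderRate))
}

# chain over one site's substrate Cs at the true marginals and odds
.siteTruthChain <- function(truthEff, id, odds) {
  te <- truthEff[truthEff$site_id == id, , drop = FALSE]
  if (!nrow(te)) return(NULL)
  te <- te[order(te$position), , drop = FALSE]
  p <- pmin(pmax(te$p_true, 1e-9), 1 - 1e-9)
  buildChain(p, rep(odds, max(0L, nrow(te) - 1L)), te$position)
}

#' Simulate replicate outcome-count tables for a library
#'
#' Per site and replicate, coverage is drawn from a negative-binomial law,
#' indel reads at the configured rate, and the remaining reads receive
#' correlated binary C-to-G edits across substrate positions sampled from
#' the same margins + odds-ratio chain the proportion model assumes (with
#' the true odds ratio), so the generator doubles as the inference oracle.
#' Each site uses a random stream derived from (seed, site id), so results
#' do not depend on site order.
#'
#' @param sites a \linkS4class{TargetSiteSet} from
#'   \code{\link{simulateLibrary}}.
#' @param truth matching truth list.
#' @param config the \code{\link{simConfig}} used.
#' @return an \linkS4class{OutcomeCounts} with \code{config$replicates}
#'   replicates per site.
#' @export
simulateReads <- function(sites, truth, config) {
  if (config$coverageMean < 1) stop("coverage mean must be >= 1",
                                    call. = FALSE)
  st <- siteTable(sites)
  rows <- vector("list", nrow(st) * config$replicates)
  ri <- 0L
  for (i in seq_len(nrow(st))) {
    id <- st$site_id[i]
    chain <- .siteTruthChain(truth$efficiency, id, truth$adjacentOdds)
    for (rep_ in seq_len(config$replicates)) {
      ri <- ri + 1L
      rows[[ri]] <- .withSeed(
        .deriveSeed(config$seed + 7919L * rep_, id), {
          cov <- rnbinom(1L, size = config$coverageDispersion,
                         mu = config$coverageMean)
          if (cov < 1L) NULL else {
            nIndel <- rbinom(1L, cov, truth$indelRate)
            nSub <- cov - nIndel
            pat <- character(0); cnt <- numeric(0)
            if (nIndel > 0L) { pat <- "INDEL"; cnt <- nIndel }
            if (nSub > 0L) {
              if (is.null(chain)) {
                pat <- c(pat, "REF"); cnt <- c(cnt, nSub)
              } else {
                X <- sampleChain(chain, nSub)
                code <- drop(X %*% 2^(seq_len(ncol(X)) - 1L))
                tab <- table(code)
                pos <- chain@positions
                pp <- vapply(as.numeric(names(tab)), function(cd)
                  makePattern(pos[bitwAnd(floor(cd / 2^(seq_along(pos) -
                                                          1L)), 1) == 1]),
                  character(1))
                pat <- c(pat, pp); cnt <- c(cnt, as.numeric(tab))
              }
            }
            if (!length(pat)) NULL else
              data.frame(site_id = id,
                         replicate = paste0("rep", rep_),
                         pattern = pat, count = cnt,
                         stringsAsFactors = FALSE)
          }
        })
    }
  }
  d <- do.call(rbind, rows)
  OutcomeCounts(d$site_id, d$replicate, d$pattern, d$count)
}

#' Simulate raw read sequences for one site
#'
#' Read-level counterpart of \code{\link{simulateReads}}: emits read
#' strings carrying C-to-G edit patterns sampled from the truth chain,
#' single-base deletions inside the protospacer for indel reads, and
#' occasional C-to-A/T bystander conversions at unedited substrate Cs.
#' Reads of reverse-orientation sites are emitted reverse-complemented so
#' that \code{\link{orientToForward}} is exercised downstream.
#'
#' @param site a one-site \linkS4class{TargetSiteSet} slice.
#' @param truth truth list from \code{\link{simulateLibrary}}.
#' @param config the \code{\link{simConfig}} used.
#' @param replicate replicate label (also salts the random stream).
#' @return character vector of read sequences.
#' @export
simulateSiteReads <- function(site, truth, config, replicate = 1L) {
  s <- siteTable(site)
  if (nrow(s) != 1L) stop("simulateSiteReads needs exactly one site")
  id <- s$site_id
  chars <- strsplit(s$sequence, "", fixed = TRUE)[[1]]
  st0 <- s$protospacer_start
  chain <- .siteTruthChain(truth$efficiency, id, truth$adjacentOdds)
  .withSeed(.deriveSeed(config$seed + 7919L * replicate, id), {
    cov <- rnbinom(1L, size = config$coverageDispersion,
                   mu = config$coverageMean)
    if (cov < 1L) cov <- 1L
    isIndel <- runif(cov) < truth$indelRate
    reads <- character(cov)
    sp <- if (is.null(chain)) integer(0) else chain@positions
    X <- if (is.null(chain) || sum(!isIndel) == 0L) NULL else
      sampleChain(chain, sum(!isIndel))
    xi <- 0L
    for (r in seq_len(cov)) {
      rc <- chars
      if (isIndel[r]) {
        del <- st0 + sample.int(20L, 1L) - 1L
        rc <- rc[-del]
      } else {
        xi <- xi + 1L
        edited <- if (is.null(X)) integer(0) else sp[X[xi, ] == 1L]
        if (length(edited)) rc[st0 + edited - 1L] <- "G"
        unedited <- setdiff(sp, edited)
        if (length(unedited) && runif(1) < truth$bystanderRate) {
          bp <- if (length(unedited) == 1L) unedited else
            sample(unedited, 1L)
          rc[st0 + bp - 1L] <- sample(c("A", "T"), 1L)
        }
      }
      reads[r] <- paste(rc, collapse = "")
    }
    if (s$strand == "reverse") reads <- reverseComplementSeq(reads)
    reads
  })
}

#' Write simulation truth as TSV
#'
#' @param truth truth list from \code{\link{simulateLibrary}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTruth <- function(truth, path) {
  write.table(truth$efficiency, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
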