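# Read classification and quantification: turn amplicon reads into edit
# calls, then into filtered, smoothed training tables with per-position
# efficiency labels.

#' Bring a read into the forward protospacer frame
#'
#' Reads sequenced in the reverse orientation are reverse-complemented so
#' that the protospacer reads 5'->3' and only C is considered as the
#' substrate nucleotide; a substitution called at protospacer position p in
#' the reverse frame maps to position 21-p in the forward frame. Reads
#' already in the forward frame are returned unchanged, so applying the
#' operation to its own output is the identity.
#'
#' @param read character vector of read sequences.
#' @param orientation \code{"forward"} or \code{"reverse"} (scalar or per
#'   read).
#' @return character vector of forward-frame reads.
#' @export
orientToForward <- function(read, orientation) {
  orientation <- rep_len(orientation, length(read))
  if (!all(orientation %in% c("forward", "reverse")))
    stop("unknown read orientation; expected forward/reverse",
         call. = FALSE)
  rev <- orientation == "reverse"
  if (any(rev)) read[rev] <- reverseComplementSeq(read[rev])
  read
}

# map reverse-frame protospacer positions to forward frame
.flipPositions <- function(p) 21L - p

#' Classify reads against a target site
#'
#' Each read is compared with the site's reference amplicon. Reads whose
#' alignment to the reference changes length inside the protospacer + PAM
#' (positions 1-23) are classified as \code{indel}; equal-length reads are
#' compared per position over protospacer positions 1-20, recording the
#' observed base at every reference C that differs (mismatches at non-C
#' positions are ignored: sequencing-error modeling is out of scope). A
#' read identical to the reference over positions 1-20 is \code{unedited}.
#' Length-discordant reads are aligned with a global affine-gap scheme
#' (match 2, mismatch -2, gap open -6, gap extend -1).
#'
#' @param reads character vector of reads, already in the forward frame
#'   (see \code{\link{orientToForward}}); each read must cover the whole
#'   reference amplicon when equal length, or be globally alignable to it.
#' @param site a one-site \linkS4class{TargetSiteSet} slice.
#' @return data.frame with columns \code{class}
#'   (\code{substitution_pattern}/\code{unedited}/\code{indel}) and
#'   \code{subs} (canonical call string such as \code{"6G+8T"}, \code{""}
#'   for unedited/indel).
#' @export
classifyReads <- function(reads, site) {
  s <- siteTable(site)
  if (nrow(s) != 1L) stop("classifyReads needs exactly one site")
  ref <- s$sequence
  st <- s$protospacer_start
  refProto <- strsplit(substr(ref, st, st + 19L), "", fixed = TRUE)[[1]]
  cpos <- which(refProto == "C")

  if (any(nchar(reads) < st + 19L))
    stop("read does not cover protospacer positions 1-20", call. = FALSE)

  # amplicon data carries few distinct genotypes: classify unique reads
  uniq <- unique(reads)
  map <- match(reads, uniq)
  n <- length(uniq)
  cls <- character(n)
  subs <- character(n)
  same <- nchar(uniq) == nchar(ref)

  # fast path: equal length, direct per-position comparison
  if (any(same)) {
    idx <- which(same)
    protoReads <- substr(uniq[idx], st, st + 19L)
    M <- matrix("", nrow = length(idx), ncol = 20L)
    for (p in 1:20) M[, p] <- substr(protoReads, p, p)
    subList <- rep("", length(idx))
    for (p in cpos) {
      diff <- M[, p] != "C"
      if (any(diff))
        subList[diff] <- ifelse(subList[diff] == "",
                                paste0(p, M[diff, p]),
                                paste0(subList[diff], "+", p, M[diff, p]))
    }
    cls[idx] <- ifelse(subList == "", "unedited", "substitution_pattern")
    subs[idx] <- subList
  }

  # slow path: length-discordant reads, batched global alignment
  if (any(!same)) {
    disc <- which(!same)
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                    mismatch = -2,
                                                    baseOnly = TRUE)
    aln <- Biostrings::pairwiseAlignment(pattern = uniq[disc],
                                         subject = ref,
                                         substitutionMatrix = mat,
                                         gapOpening = 6, gapExtension = 1,
                                         type = "global")
    pas <- as.character(Biostrings::alignedPattern(aln))
    sas <- as.character(Biostrings::alignedSubject(aln))
    for (k in seq_along(disc)) {
      r <- .alignClassify(pas[k], sas[k], st, cpos)
      cls[disc[k]] <- r$class
      subs[disc[k]] <- r$subs
    }
  }
  data.frame(class = cls[map], subs = subs[map], stringsAsFactors = FALSE)
}

# walk one aligned read/reference pair; gap within protospacer+PAM
# (positions 1-23) => indel, otherwise substitutions read off the aligned
# columns at reference-C positions
.alignClassify <- function(alnPattern, alnSubject, st, cpos) {
  pa <- strsplit(alnPattern, "", fixed = TRUE)[[1]]
  sa <- strsplit(alnSubject, "", fixed = TRUE)[[1]]
  refPos <- cumsum(sa != "-")
  inCore <- refPos >= st & refPos <= st + 22L
  gapCol <- pa == "-" | sa == "-"
  if (any(gapCol & inCore))
    return(list(class = "indel", subs = ""))
  toks <- character(0)
  for (p in cpos) {
    col <- which(refPos == (st + p - 1L) & sa != "-")[1]
    if (is.na(col)) return(list(class = "indel", subs = ""))
    if (pa[col] != "C" && pa[col] != "-")
      toks <- c(toks, paste0(p, pa[col]))
  }
  if (length(toks)) list(class = "substitution_pattern",
                         subs = paste(toks, collapse = "+"))
  else list(class = "unedited", subs = "")
}

#' On-target editing efficiency
#'
#' The number of reads containing only the intended edits (no bystander
#' substitutions) divided by the total number of reads, indel reads
#' included in the denominator.
#'
#' @param calls data.frame from \code{\link{classifyReads}}.
#' @param intendedEdits character vector of intended position/base tokens
#'   (e.g. \code{c("6G")}) or a single pattern string \code{"6G+8G"}.
#' @return numeric in [0,1].
#' @export
onTargetEfficiency <- function(calls, intendedEdits) {
  if (nrow(calls) == 0L) stop("empty call list", call. = FALSE)
  if (length(intendedEdits) == 0L || !nzchar(intendedEdits[1]))
    stop("intendedEdits must be nonempty", call. = FALSE)
  target <- canonicalPattern(paste(intendedEdits, collapse = "+"),
                             allowBystander = TRUE)
  sum(calls$class == "substitution_pattern" & calls$subs == target) /
    nrow(calls)
}

#' Indel frequency
#'
#' The number of reads including indels divided by the total number of
#' reads.
#'
#' @param calls data.frame from \code{\link{classifyReads}}.
#' @return numeric in [0,1].
#' @export
indelFrequency <- function(calls) {
  if (nrow(calls) == 0L) stop("empty call list", call. = FALSE)
  mean(calls$class == "indel")
}

#' Collapse read calls into an outcome-count table
#'
#' C-to-G substitutions define the modeled pattern; A/T bystander bases are
#' dropped from the pattern (a read with only bystander conversions counts
#' as REF in the modeled outcome space).
#'
#' @param calls data.frame from \code{\link{classifyReads}}.
#' @param site_id,replicate scalars labeling the calls.
#' @return an \linkS4class{OutcomeCounts}.
#' @export
callsToOutcomeCounts <- function(calls, site_id, replicate = "rep1") {
  pat <- vapply(seq_len(nrow(calls)), function(i) {
    if (calls$class[i] == "indel") return("INDEL")
    if (calls$subs[i] == "") return("REF")
    toks <- strsplit(calls$subs[i], "+", fixed = TRUE)[[1]]
    toks <- toks[grepl("G$", toks)]
    if (!length(toks)) return("REF")
    makePattern(as.integer(sub("G$", "", toks)))
  }, character(1))
  tab <- table(pat)
  OutcomeCounts(rep(site_id, length(tab)), rep(replicate, length(tab)),
                names(tab), as.numeric(tab))
}

#' Assemble a filtered, smoothed training table with efficiency labels
#'
#' Reproduces the library preprocessing: (1) indel reads are discarded;
#' (2) any replicate whose remaining total is below \code{minReads} is
#' dropped; (3) surviving replicates are summed per pattern; (4) add-one
#' smoothing puts one count on every edited outcome in the site's outcome
#' space (all subsets of its substrate-C positions up to
#' \code{maxPatternOrder}, plus any higher-order pattern actually
#' observed); (5) the per-position efficiency label is the smoothed count
#' of reads edited at that position over the smoothed total. Sites with no
#' surviving replicate are omitted (and reported), not an error.
#'
#' @param counts an \linkS4class{OutcomeCounts} with one or more
#'   replicates per site.
#' @param sites the matching \linkS4class{TargetSiteSet}.
#' @param minReads replicate-level read filter (drop totals < minReads).
#' @param maxPatternOrder highest pattern order enumerated for smoothing.
#' @return list with elements \code{labels} (data.frame site_id, position,
#'   efficiency, coverage), \code{counts} (summed + smoothed
#'   \linkS4class{OutcomeCounts}, replicate \code{"pooled"}),
#'   \code{dropped} (data.frame of omitted site/replicate records).
#' @export
assembleTrainingTable <- function(counts, sites, minReads = 100,
                                  maxPatternOrder = 2L) {
  d <- countsTable(counts)
  st <- siteTable(sites)
  labels <- list(); pooled <- list(); dropped <- list()
  for (id in unique(d$site_id)) {
    ds <- d[d$site_id == id & d$pattern != "INDEL", , drop = FALSE]
    tot <- tapply(ds$count, ds$replicate, sum)
    keep <- names(tot)[tot >= minReads]
    for (r in setdiff(names(tot), keep))
      dropped[[length(dropped) + 1L]] <-
        data.frame(site_id = id, replicate = r, reads = tot[[r]],
                   stringsAsFactors = FALSE)
    if (!length(keep)) next
    ds <- ds[ds$replicate %in% keep, , drop = FALSE]
    agg <- tapply(ds$count, ds$pattern, sum)
    pat <- names(agg); cnt <- as.numeric(agg)

    sp <- substratePositions(sites, id)
    if (!length(sp)) next  # no substrate C: nothing to label or smooth
    space <- .patternSpace(sp, maxPatternOrder)
    miss <- setdiff(space, pat)
    pat <- c(pat, miss); cnt <- c(cnt, rep(0, length(miss)))
    edited <- pat != "REF"
    cnt[edited] <- cnt[edited] + 1          # add-one smoothing
    totalRaw <- sum(agg)
    totalSm <- sum(cnt)

    posList <- patternPositions(pat)
    eff <- vapply(sp, function(p)
      sum(cnt[vapply(posList, function(q) p %in% q, logical(1))]) / totalSm,
      numeric(1))
    labels[[length(labels) + 1L]] <-
      data.frame(site_id = id, position = sp, efficiency = eff,
                 coverage = totalRaw, stringsAsFactors = FALSE)
    pooled[[length(pooled) + 1L]] <-
      data.frame(site_id = id, replicate = "pooled", pattern = pat,
                 count = cnt, stringsAsFactors = FALSE)
  }
  dropDf <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(site_id = character(0), replicate = character(0),
               reads = numeric(0))
  if (nrow(dropDf))
    message("assembleTrainingTable: dropped ", nrow(dropDf),
            " replicate(s) below ", minReads, " reads")
  labDf <- if (length(labels)) do.call(rbind, labels) else
    data.frame(site_id = character(0), position = integer(0),
               efficiency = numeric(0), coverage = numeric(0))
  poolDf <- do.call(rbind, pooled)
  pooledCounts <- if (is.null(poolDf))
    new("OutcomeCounts",
        counts = data.frame(site_id = character(0),
                            replicate = character(0),
                            pattern = character(0), count = numeric(0)))
  else OutcomeCounts(poolDf$site_id, poolDf$replicate, poolDf$pattern,
                     poolDf$count)
  list(labels = labDf, counts = pooledCounts, dropped = dropDf)
}

# all C-to-G patterns over substrate positions up to a given order,
# REF included
.patternSpace <- function(positions, maxOrder = 2L) {
  out <- "REF"
  for (k in seq_len(min(maxOrder, length(positions)))) {
    combs <- utils::combn(seq_along(positions), k, simplify = FALSE)
    out <- c(out, vapply(combs, function(i) makePattern(positions[i]),
                         character(1)))
  }
  out
}

#' Restrict labels to the high-confidence editing window
#'
#' Retains (site, position) pairs whose targeted C lies at protospacer
#' positions 4-7 and whose coverage strictly exceeds \code{minCoverage}.
#'
#' @param labels data.frame from \code{\link{assembleTrainingTable}}.
#' @param window integer positions retained (default 4:7).
#' @param minCoverage strict lower bound on coverage (default 100).
#' @return filtered data.frame.
#' @export
windowFilter <- function(labels, window = 4:7, minCoverage = 100) {
  labels[labels$position %in% window & labels$coverage > minCoverage, ,
         drop = FALSE]
}
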