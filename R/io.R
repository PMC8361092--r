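# Readers/writers for the site-table, outcome-table, prediction and
# proportion TSV formats. All readers validate and reject malformed input;
# all writers emit a canonical row order so identical inputs serialize to
# byte-identical files.

#' Read a target-site table (TSV)
#'
#' Expects a tab-delimited file with header columns \code{site_id},
#' \code{sequence}, \code{protospacer_start}, \code{strand}. Every row is
#' validated against the \linkS4class{TargetSiteSet} invariants; row order
#' is preserved.
#'
#' @param path file path.
#' @return a \linkS4class{TargetSiteSet}.
#' @export
readSiteTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("site_id", "sequence", "protospacer_start", "strand")
  if (!all(need %in% names(d)))
    stop("site table ", path, " lacks columns: ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  ps <- suppressWarnings(as.integer(d$protospacer_start))
  bad <- which(is.na(ps))
  if (length(bad))
    stop("parse error in ", path, " line ", bad[1] + 1L,
         ": protospacer_start is not an integer", call. = FALSE)
  TargetSiteSet(d$site_id, d$sequence, ps, d$strand)
}

#' Write a target-site table (TSV)
#'
#' @param sites a \linkS4class{TargetSiteSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSiteTable <- function(sites, path) {
  stopifnot(is(sites, "TargetSiteSet"))
  write.table(siteTable(sites), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read an outcome-count table (TSV)
#'
#' Columns \code{site_id}, \code{replicate}, \code{pattern}, \code{count}.
#' Patterns are canonicalized on read (\code{"8G+6G"} becomes
#' \code{"6G+8G"}); unknown tokens or negative counts are errors.
#'
#' @param path file path.
#' @return an \linkS4class{OutcomeCounts}.
#' @export
readOutcomeTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- read.delim(path, colClasses = c("character", "character",
                                       "character", "numeric"),
                  check.names = FALSE)
  need <- c("site_id", "replicate", "pattern", "count")
  if (!all(need %in% names(d)))
    stop("outcome table ", path, " lacks columns: ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  if (any(d$count < 0))
    stop("negative count in ", path, " for site ",
         d$site_id[which(d$count < 0)[1]], call. = FALSE)
  OutcomeCounts(d$site_id, d$replicate, d$pattern, d$count)
}

#' Write an outcome-count table (TSV)
#'
#' Rows are emitted ordered by site, replicate and canonical pattern order
#' (REF, INDEL, then patterns by position), so serialization is
#' deterministic.
#'
#' @param x an \linkS4class{OutcomeCounts}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeOutcomeTable <- function(x, path) {
  stopifnot(is(x, "OutcomeCounts"))
  d <- countsTable(x)
  rank <- ifelse(d$pattern == "REF", 0L, ifelse(d$pattern == "INDEL", 1L, 2L))
  key <- vapply(patternPositions(d$pattern), function(p)
    paste(sprintf("%02d", p), collapse = ","), character(1))
  d <- d[order(d$site_id, d$replicate, rank, nchar(key), key), , drop = FALSE]
  d$count <- format(d$count, scientific = FALSE, trim = TRUE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write per-position efficiency predictions (TSV)
#'
#' Columns \code{site_id}, \code{position}, \code{efficiency}; positions
#' without a reference C carry \code{NA}.
#'
#' @param x data.frame of predictions.
#' @param path file path.
#' @return the data.frame (read) or \code{path} invisibly (write).
#' @export
writePredictions <- function(x, path) {
  stopifnot(all(c("site_id", "position", "efficiency") %in% names(x)))
  x <- x[order(x$site_id, x$position), c("site_id", "position",
                                         "efficiency")]
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePredictions
#' @export
readPredictions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- read.delim(path)
  stopifnot(all(c("site_id", "position", "efficiency") %in% names(d)))
  d$position <- as.integer(d$position)
  d
}

#' Read/write outcome-proportion predictions (TSV)
#'
#' Columns \code{site_id}, \code{pattern}, \code{probability}.
#'
#' @param x data.frame of proportions.
#' @param path file path.
#' @return the data.frame (read) or \code{path} invisibly (write).
#' @export
writeProportions <- function(x, path) {
  stopifnot(all(c("site_id", "pattern", "probability") %in% names(x)))
  x <- do.call(rbind, lapply(split(x, x$site_id), function(g)
    g[.patternOrder(g$pattern), , drop = FALSE]))
  write.table(x[, c("site_id", "pattern", "probability")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeProportions
#' @export
readProportions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- read.delim(path, colClasses = c("character", "character", "numeric"))
  d$pattern <- canonicalPattern(d$pattern)
  d
}

#' Read raw reads from FASTA/FASTQ (plain or gzip)
#'
#' Thin wrapper over \code{Biostrings::readDNAStringSet}; format is chosen
#' by file extension.
#'
#' @param path path to a .fasta/.fa/.fastq/.fq file, optionally .gz.
#' @return character vector of read sequences.
#' @export
readReads <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  base <- sub("\\.gz$", "", path)
  fmt <- if (grepl("\\.(fastq|fq)$", base)) "fastq" else "fasta"
  as.character(Biostrings::readDNAStringSet(path, format = fmt))
}

#' Write reads as FASTA
#'
#' @param reads character vector of sequences.
#' @param path output path (.fasta, optionally .gz).
#' @param prefix read-name prefix.
#' @return \code{path}, invisibly.
#' @export
writeReadsFasta <- function(reads, path, prefix = "read") {
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- paste0(prefix, seq_along(reads))
  Biostrings::writeXStringSet(x, path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
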