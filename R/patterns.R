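# Canonical serialization of edit patterns.
#
# A pattern is "REF" (unedited), "INDEL", or a "+"-joined list of
# position/base tokens such as "6G" or "4G+7G", positions sorted ascending.
# Only C-to-G substitutions belong to the modeled outcome space; read-level
# call strings may additionally carry A/T bystander bases (e.g. "6G+8T").

#' Canonicalize an edit-pattern string
#'
#' Validates tokens and sorts them by protospacer position so that, e.g.,
#' \code{"8G+6G"} becomes \code{"6G+8G"}. \code{"REF"} and \code{"INDEL"}
#' pass through unchanged.
#'
#' @param x character vector of pattern strings.
#' @param allowBystander also accept A/T observed bases (read-level calls).
#' @return character vector of canonical pattern strings.
#' @export
canonicalPattern <- function(x, allowBystander = FALSE) {
  vapply(x, function(p) {
    if (p %in% c("REF", "INDEL")) return(p)
    toks <- strsplit(p, "+", fixed = TRUE)[[1]]
    re <- if (allowBystander) "^([1-9]|1[0-9]|20)[AGT]$" else
      "^([1-9]|1[0-9]|20)G$"
    if (length(toks) == 0L || !all(grepl(re, toks)))
      stop("unknown pattern token in '", p, "'", call. = FALSE)
    pos <- as.integer(sub("[AGT]$", "", toks))
    if (anyDuplicated(pos))
      stop("duplicate position in pattern '", p, "'", call. = FALSE)
    paste(toks[order(pos)], collapse = "+")
  }, character(1), USE.NAMES = FALSE)
}

#' Positions carried by a pattern string
#'
#' @param x character vector of canonical patterns.
#' @return list of sorted integer position vectors (empty for REF/INDEL).
#' @export
patternPositions <- function(x) {
  lapply(x, function(p) {
    if (p %in% c("REF", "INDEL")) return(integer(0))
    as.integer(sub("[AGT]$", "", strsplit(p, "+", fixed = TRUE)[[1]]))
  })
}

#' Build a canonical pattern string from positions (C-to-G edits)
#'
#' @param positions integer vector of protospacer positions; empty gives
#'   \code{"REF"}.
#' @param bases observed bases, recycled; defaults to \code{"G"}.
#' @return canonical pattern string.
#' @export
makePattern <- function(positions, bases = "G") {
  if (length(positions) == 0L) return("REF")
  bases <- rep_len(bases, length(positions))
  o <- order(positions)
  paste0(positions[o], bases[o], collapse = "+")
}

# sort key placing REF first, INDEL second, then patterns by their
# position vector; used for byte-stable serialization
.patternOrder <- function(x) {
  rank <- ifelse(x == "REF", 0L, ifelse(x == "INDEL", 1L, 2L))
  key <- vapply(patternPositions(x), function(p)
    paste(sprintf("%02d", p), collapse = ","), character(1))
  order(rank, nchar(key), key)
}
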