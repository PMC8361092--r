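#' @importFrom stats rnorm rbinom rnbinom runif cor sd setNames
#' @importFrom utils head read.delim write.table
NULL

BASES <- c("A", "C", "G", "T")
SYMBOLS <- c("A", "C", "G", "T", "PAD")

.sigmoid <- function(x) 1 / (1 + exp(-x))

.logit <- function(p) log(p / (1 - p))

#' Derive a reproducible child seed from a master seed and a string key
#'
#' Hashes the key with a 31-adic rolling hash modulo a Mersenne prime and
#' mixes in the master seed, so per-site random streams do not depend on the
#' order in which sites are processed.
#'
#' @param seed master integer seed.
#' @param key character scalar (e.g. a site id).
#' @return an integer seed in \code{[0, 2^31)}.
#' @keywords internal
.deriveSeed <- function(seed, key) {
  mod <- 2147483647
  h <- as.numeric(seed) %% mod
  for (v in utf8ToInt(key)) h <- (h * 31 + v) %% mod
  as.integer(h)
}

# run code under a temporary RNG state, restoring the caller's stream
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Reverse complement of a nucleotide string
#'
#' @param x character vector of A/C/G/T strings.
#' @return character vector of reverse complements.
#' @export
reverseComplementSeq <- function(x) {
  vapply(x, function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

.checkAlphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(what, " contains non-A/C/G/T characters (ambiguity codes are ",
         "rejected): ", paste(head(x[bad], 3), collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

.pearson <- function(x, y) {
  if (length(x) < 2L || sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

.rmse <- function(x, y) sqrt(mean((x - y)^2))
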