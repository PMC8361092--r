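# Programmatic fixtures: sites built from explicit protospacers with
# deterministic flanks, so tests control exactly where the substrate Cs sit.

# build a one-site TargetSiteSet around a given 20-nt protospacer
makeSite <- function(protospacer, id = "s1", pam = "AGG",
                     leftFlank = "ATGATGATGA", rightFlank = "TGATGATGAT",
                     strand = "forward") {
  stopifnot(nchar(protospacer) == 20L)
  TargetSiteSet(id, paste0(leftFlank, protospacer, pam, rightFlank),
                nchar(leftFlank) + 1L, strand)
}

# protospacer with Cs only at the given positions (A elsewhere), and
# prescribed neighbors where requested
protoWithCs <- function(cPositions, fill = "A") {
  p <- rep(fill, 20)
  p[cPositions] <- "C"
  paste(p, collapse = "")
}

# calls data.frame shaped like classifyReads() output
makeCalls <- function(class, subs = "") {
  data.frame(class = class, subs = rep_len(subs, length(class)),
             stringsAsFactors = FALSE)
}
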