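#' @keywords internal
"_PACKAGE"

#' @importFrom stats kruskal.test t.test ks.test lm nls coef predict sd
#'   rnorm rbinom runif rbeta p.adjust pnorm pchisq setNames complete.cases
#'   var resid
#' @importFrom utils write.table read.delim head
NULL

# Reverse complement of a plain character vector of DNA strings.
# Thin wrapper over Biostrings so ambiguity codes and N are handled.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Split DNA strings into a list of character vectors of single bases.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)

# Derive a stage-specific RNG seed from a root seed and a stream label,
# keeping the result a valid 32-bit R integer.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

# Hamming distance between a single pattern and the prefix of each subject,
# vectorised over subjects. Subjects shorter than the pattern count the
# missing positions as mismatches.
prefix_mismatches <- function(subjects, pattern) {
  k <- nchar(pattern)
  pat <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  mm <- integer(length(subjects))
  pre <- substr(subjects, 1L, k)
  for (i in seq_len(k)) {
    b <- substr(pre, i, i)
    mm <- mm + as.integer(b != pat[i])  # "" (read too short) counts as mismatch
  }
  mm
}

`%||%` <- function(a, b) if (is.null(a)) b else a
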