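.abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Derive a stage seed from the global seed
#'
#' All randomness in the package flows from one global integer seed; each
#' stage (reference, B sequence, reads per genotype, contigs, Ct table, ...)
#' draws from its own stream derived deterministically from that seed and a
#' stage label, so regenerating one stage never perturbs another.
#'
#' @param seed global integer seed.
#' @param stage character stage label.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, stage) {
  if (length(seed) != 1L || is.na(seed)) .abort("seed must be a single integer")
  seed <- as.numeric(seed)
  h <- 0
  for (ch in utf8ToInt(as.character(stage))) h <- (h * 31 + ch) %% 32749
  as.integer(((abs(seed) %% 65521) * 32749 + h) %% 2147483647)
}

# run code under a derived seed without disturbing the caller's RNG state
.with_stage_seed <- function(seed, stage, code) {
  withr::with_seed(derive_seed(seed, stage), code)
}

.DNA_BASES <- c("A", "C", "G", "T")

# uniform random DNA string of length n (assumes RNG already seeded)
.random_dna <- function(n) {
  paste(sample(.DNA_BASES, n, replace = TRUE), collapse = "")
}

# substitute each base with a uniformly chosen different base
.mutate_bases <- function(bases) {
  vapply(bases, function(b) sample(setdiff(.DNA_BASES, b), 1L), "",
         USE.NAMES = FALSE)
}

.check_dna_alphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad))
    .abort("%s contains characters outside A/C/G/T: %s", what,
           paste(head(x[bad], 3), collapse = ", "))
  invisible(x)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# count mismatches between equal-length strings (byte-wise)
.hamming <- function(a, b) {
  mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b,
         USE.NAMES = FALSE)
}
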