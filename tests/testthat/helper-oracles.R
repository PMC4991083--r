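# Independent oracles and small fixture builders used across the suite.

# full Smith-Waterman local score via Biostrings (independent of the
# package's seed-and-extend implementation)
sw_oracle_score <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(a, b, type = "local",
                                substitutionMatrix = mat,
                                gapOpening = 4, gapExtension = 1,
                                scoreOnly = TRUE)
}

# exhaustive single-read placement: best Hamming position(s) over every
# offset of every scaffold
brute_map <- function(read, reference, max_mm = 2L) {
  best_mm <- Inf; best <- list()
  rl <- nchar(read)
  for (sc in names(reference)) {
    ref <- as.character(reference[[sc]])
    for (p in 0:(nchar(ref) - rl)) {
      mm <- sum(charToRaw(read) != charToRaw(substring(ref, p + 1, p + rl)))
      if (mm < best_mm) { best_mm <- mm; best <- list(c(sc = sc, pos = p)) }
      else if (mm == best_mm) best <- c(best, list(c(sc = sc, pos = p)))
    }
  }
  if (best_mm > max_mm) return(NULL)
  list(mm = best_mm, hits = best)
}

# position-by-position in-silico PCR scan, independent of Biostrings matching
brute_pcr <- function(template, primers, max_product = 1000L, m_internal = 3L) {
  tpl <- strsplit(toupper(template), "")[[1]]
  n <- length(tpl)
  revcomp_chr <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  primes_at <- function(oriented, start0, three_left) {
    L <- nchar(oriented)
    if (start0 < 0 || start0 + L > n) return(NA)
    mm <- strsplit(oriented, "")[[1]] != tpl[(start0 + 1):(start0 + L)]
    if (three_left) {
      if (mm[1]) return(FALSE)
      term <- mm[1:min(5, L)]; inner <- if (L > 5) mm[6:L] else logical(0)
    } else {
      if (mm[L]) return(FALSE)
      term <- mm[max(1, L - 4):L]; inner <- if (L > 5) mm[1:(L - 5)] else logical(0)
    }
    sum(term) <= 1 && sum(inner) <= m_internal
  }
  fwd <- list(); rev <- list()
  for (p in primers) {
    seqp <- if (inherits(p, "primer")) p$sequence else as.character(p)
    idp <- if (inherits(p, "primer")) p$id else "primer"
    L <- nchar(seqp); rc <- revcomp_chr(seqp)
    for (s in 0:(n - L)) {
      if (isTRUE(primes_at(seqp, s, three_left = FALSE)))
        fwd[[length(fwd) + 1]] <- data.frame(id = idp, start = s, end = s + L)
      if (isTRUE(primes_at(rc, s, three_left = TRUE)))
        rev[[length(rev) + 1]] <- data.frame(id = idp, start = s, end = s + L)
    }
  }
  out <- list()
  for (f in fwd) for (r in rev) {
    len <- r$end - f$start
    if (len > 0 && len <= max_product)
      out[[length(out) + 1]] <- data.frame(start = f$start, end = r$end,
                                           length = len, fwd_id = f$id,
                                           rev_id = r$id)
  }
  if (length(out) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), fwd_id = character(0),
                      rev_id = character(0)))
  do.call(rbind, out)
}

# cohort without reads or Ct table: enough for design/PCR round trips
make_light_cohort <- function(seed, n_contigs = 40L, ...) {
  spec <- truth_spec(seed = seed, ...)
  reference <- make_reference(spec$seed, spec$scaffold_lengths)
  b <- make_b_sequence(reference, spec)
  contigs <- simulate_b_contigs(b, n_contigs, seed = spec$seed)
  list(spec = spec, reference = reference, b = b, contigs = contigs)
}

# depth_profile built directly from window counts (library size given)
fake_profile <- function(counts, library_size, window_size = 100L,
                         sample_id = "s") {
  lens <- vapply(counts, function(x) length(x) * window_size, 1L)
  structure(list(sample_id = sample_id, genotype = NA_character_,
                 window_size = as.integer(window_size), counts = counts,
                 scaffold_lengths = lens, library_size = library_size),
            class = "depth_profile")
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

mutate_at <- function(seq, pos0, base) {
  substring(seq, pos0 + 1, pos0 + 1) <- base
  seq
}
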