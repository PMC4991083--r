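#' Local alignment of a contig against a reference sequence
#'
#' Seed-and-extend local alignment: exact k-mer seeds anchor the contig on the
#' reference (both orientations), and a Smith-Waterman pass with affine gaps
#' (match +1, mismatch -2, gap open -4, gap extend -1 per base) is run on the
#' seeded reference window. The best-scoring orientation wins. With no seed
#' match the result is a "no alignment" object, not an error.
#'
#' @param contig character or [Biostrings::DNAString] (length >= `k`).
#' @param reference character or [Biostrings::DNAString].
#' @param k seed k-mer length, default 12.
#' @param margin extra reference bases kept on each side of the seeded
#'   window before the Smith-Waterman pass.
#' @param match,mismatch,gap_open,gap_extend alignment scores.
#' @return object of class `contig_alignment`: list with `aligned` (logical),
#'   `score`, `strand` ("+"/"-"), `contig_start`, `contig_end`, `ref_start`,
#'   `ref_end` (0-based half-open; contig coordinates are on the original
#'   contig orientation), `ops` (character over M/I/D), `mismatches`
#'   (data.frame contig_pos, ref_pos, contig_base, ref_base) and
#'   `n_mismatches`.
#' @export
align_contig <- function(contig, reference, k = 12L, margin = 50L,
                         match = 1, mismatch = -2, gap_open = 4,
                         gap_extend = 1) {
  contig <- as.character(contig); reference <- as.character(reference)
  k <- as.integer(k)
  if (nchar(contig) < k) .abort("contig shorter than seed length k")
  best <- NULL
  for (strand in c("+", "-")) {
    query <- if (strand == "+") contig else .revcomp(contig)
    win <- .seed_window(query, reference, k, margin)
    if (is.null(win)) next
    aln <- .sw_align_cpp(substring(query, win$q_lo, win$q_hi),
                         substring(reference, win$r_lo, win$r_hi),
                         match, mismatch, gap_open, gap_extend)
    if (aln$score <= 0) next
    if (is.null(best) || aln$score > best$aln$score)
      best <- list(aln = aln, strand = strand, win = win, query = query)
  }
  if (is.null(best))
    return(structure(list(aligned = FALSE, score = 0), class = "contig_alignment"))
  aln <- best$aln; win <- best$win
  q_start <- win$q_lo - 1L + aln$a_start   # 0-based on query orientation
  q_end <- win$q_lo - 1L + aln$a_end
  r_start <- win$r_lo - 1L + aln$b_start
  r_end <- win$r_lo - 1L + aln$b_end
  mm_q <- win$q_lo - 1L + aln$mm_a
  mm_r <- win$r_lo - 1L + aln$mm_b
  n <- nchar(contig)
  if (best$strand == "+") {
    c_start <- q_start; c_end <- q_end; mm_c <- mm_q
  } else {
    # map query (revcomp) coordinates back to the original contig
    c_start <- n - q_end; c_end <- n - q_start
    mm_c <- n - 1L - mm_q
  }
  if (length(mm_q) == 0L) {
    mism <- data.frame(contig_pos = integer(0), ref_pos = integer(0),
                       contig_base = character(0), ref_base = character(0))
  } else {
    mism <- data.frame(contig_pos = mm_c, ref_pos = mm_r,
                       contig_base = substring(best$query, mm_q + 1L, mm_q + 1L),
                       ref_base = substring(reference, mm_r + 1L, mm_r + 1L),
                       stringsAsFactors = FALSE)
    mism <- mism[order(mism$ref_pos), , drop = FALSE]
  }
  structure(list(aligned = TRUE, score = aln$score, strand = best$strand,
                 contig_start = c_start, contig_end = c_end,
                 ref_start = r_start, ref_end = r_end,
                 ops = aln$ops, mismatches = mism,
                 n_mismatches = nrow(mism)),
            class = "contig_alignment")
}

# exact k-mer seeding: returns 1-based inclusive query/reference windows
# covering all seed hits of the dominant diagonal band, or NULL if no seed
.seed_window <- function(query, reference, k, margin) {
  n <- nchar(query)
  starts <- seq(1L, n - k + 1L, by = max(1L, k %/% 2L))
  if (!(n - k + 1L) %in% starts) starts <- c(starts, n - k + 1L)
  diags <- integer(0); q_hits <- integer(0); r_hits <- integer(0)
  for (s in starts) {
    kmer <- substring(query, s, s + k - 1L)
    hits <- Biostrings::start(Biostrings::matchPattern(kmer, Biostrings::DNAString(reference)))
    if (length(hits) == 0L) next
    diags <- c(diags, hits - s)
    q_hits <- c(q_hits, rep(s, length(hits)))
    r_hits <- c(r_hits, hits)
  }
  if (length(diags) == 0L) return(NULL)
  # keep seeds near the most common diagonal (within one query length)
  d0 <- diags[which.max(tabulate(match(diags, unique(diags))))]
  keep <- abs(diags - d0) <= n
  r_lo <- max(1L, min(r_hits[keep]) - (min(q_hits[keep]) - 1L) - margin)
  r_hi <- min(nchar(reference),
              max(r_hits[keep] + k - 1L) + (n - max(q_hits[keep]) - k + 1L) + margin)
  list(q_lo = 1L, q_hi = n, r_lo = r_lo, r_hi = r_hi)
}

#' Column-wise consensus of pre-aligned reference sequences
#'
#' Takes two or more equal-length (pre-aligned, substitution-only) sequences
#' and returns the column-majority consensus. A strict majority wins its
#' column; ties are written as the IUPAC code of the tied bases and the
#' column is non-conserved. A column is conserved only when every sequence
#' agrees.
#'
#' @param sequences [Biostrings::DNAStringSet] (or character vector) of >= 2
#'   equal-length sequences.
#' @return object of class `consensus_alignment`: list with `sequences`,
#'   `consensus` (character string, possibly with IUPAC codes) and
#'   `conserved` (logical per column).
#' @export
build_consensus <- function(sequences) {
  sequences <- Biostrings::DNAStringSet(sequences)
  if (length(sequences) < 2L) .abort("consensus needs at least 2 sequences")
  if (length(unique(Biostrings::width(sequences))) != 1L)
    .abort("sequences must be pre-aligned to equal length")
  mat <- Biostrings::consensusMatrix(sequences)[.DNA_BASES, , drop = FALSE]
  n <- length(sequences)
  cons <- character(ncol(mat)); conserved <- logical(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    cnt <- mat[, j]
    mx <- max(cnt)
    top <- .DNA_BASES[cnt == mx]
    if (length(top) == 1L) {
      cons[j] <- top
      conserved[j] <- mx == n
    } else {
      cons[j] <- Biostrings::mergeIUPACLetters(paste(top, collapse = ""))
      conserved[j] <- FALSE
    }
  }
  structure(list(sequences = sequences,
                 consensus = paste(cons, collapse = ""),
                 conserved = conserved),
            class = "consensus_alignment")
}

#' Call B-diagnostic variants from a contig alignment
#'
#' A substitution qualifies as B-diagnostic when the contig base differs from
#' the consensus at a column where all reference sequences agree, and at
#' least `min_flank` conserved columns flank the site on both sides (so
#' primers anchored there sit in sequence shared by B and non-B templates).
#'
#' @param alignment a `contig_alignment` of the contig against the sequence
#'   the consensus was built on (same coordinate frame).
#' @param consensus a `consensus_alignment`.
#' @param min_flank minimum conserved run on each side (bp), default 20.
#' @return data.frame of variants: `position` (0-based consensus coordinate),
#'   `consensus_base`, `b_base`, `flank_left`, `flank_right`, `contig_pos`.
#' @export
call_diagnostic_variants <- function(alignment, consensus, min_flank = 20L) {
  empty <- data.frame(position = integer(0), consensus_base = character(0),
                      b_base = character(0), flank_left = integer(0),
                      flank_right = integer(0), contig_pos = integer(0))
  if (!isTRUE(alignment$aligned)) return(empty)
  ncol_cons <- nchar(consensus$consensus)
  if (alignment$ref_start >= ncol_cons || alignment$ref_end <= 0L)
    .abort("alignment does not overlap the consensus coordinates")
  conserved <- consensus$conserved
  runs <- .conserved_run_lengths(conserved)
  mm <- alignment$mismatches
  if (nrow(mm) == 0L) return(empty)
  keep <- logical(nrow(mm))
  fl <- fr <- integer(nrow(mm))
  for (i in seq_len(nrow(mm))) {
    p <- mm$ref_pos[i] + 1L            # 1-based column
    if (p < 1L || p > ncol_cons) next
    if (!conserved[p]) next
    if (substring(consensus$consensus, p, p) != mm$ref_base[i]) next
    fl[i] <- runs$left[p]; fr[i] <- runs$right[p]
    keep[i] <- fl[i] >= min_flank && fr[i] >= min_flank
  }
  if (!any(keep)) return(empty)
  data.frame(position = mm$ref_pos[keep],
             consensus_base = mm$ref_base[keep],
             b_base = mm$contig_base[keep],
             flank_left = fl[keep], flank_right = fr[keep],
             contig_pos = mm$contig_pos[keep],
             stringsAsFactors = FALSE)
}

# for each position: length of the conserved run strictly left / right of it
.conserved_run_lengths <- function(conserved) {
  n <- length(conserved)
  left <- integer(n); right <- integer(n)
  run <- 0L
  for (i in seq_len(n)) {
    left[i] <- run
    run <- if (conserved[i]) run + 1L else 0L
  }
  run <- 0L
  for (i in rev(seq_len(n))) {
    right[i] <- run
    run <- if (conserved[i]) run + 1L else 0L
  }
  list(left = left, right = right)
}
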