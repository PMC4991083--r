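#' Map reads to a reference by exact k-prefix seeding
#'
#' A deliberately simple single-end mapper so synthetic cohorts need no
#' external aligner: each read is anchored at every reference position whose
#' k-prefix matches the read's first k bases exactly, then verified over the
#' full read length by Hamming distance. The read is placed at the unique
#' best position with at most `max_mismatches` mismatches; reads whose best
#' distance is tied across several positions are discarded and counted as
#' ambiguous. Forward strand only, matching the simulator's read model.
#'
#' @param reads a [Biostrings::DNAStringSet] or a `read_set` from
#'   [simulate_reads()].
#' @param reference reference [Biostrings::DNAStringSet].
#' @param k seed (prefix) length; must not exceed the shortest read.
#' @param max_mismatches maximum full-length Hamming distance (default 2).
#' @return list with `placements` (data.frame qname, rname, pos [0-based],
#'   mismatches), `n_unmapped`, `n_ambiguous`.
#' @export
map_reads_exact <- function(reads, reference, k = 31L, max_mismatches = 2L) {
  if (inherits(reads, "read_set")) reads <- reads$reads
  k <- as.integer(k)
  widths <- Biostrings::width(reads)
  if (length(reads) == 0L)
    return(list(placements = data.frame(qname = character(0),
                                        rname = character(0),
                                        pos = integer(0),
                                        mismatches = integer(0)),
                n_unmapped = 0L, n_ambiguous = 0L))
  if (k > min(widths)) .abort("seed length k exceeds the shortest read")
  prefixes <- Biostrings::subseq(reads, 1L, k)
  pd <- Biostrings::PDict(prefixes)
  read_chr <- as.character(reads)
  cand <- list()
  for (sc in names(reference)) {
    hits <- Biostrings::matchPDict(pd, reference[[sc]])
    starts <- Biostrings::startIndex(hits)
    n_per <- lengths(starts)
    if (sum(n_per) == 0L) next
    cand[[sc]] <- data.frame(read = rep(seq_along(reads), n_per),
                             rname = sc,
                             pos = unlist(starts) - 1L,
                             stringsAsFactors = FALSE)
  }
  if (length(cand) == 0L)
    return(list(placements = data.frame(qname = character(0),
                                        rname = character(0),
                                        pos = integer(0),
                                        mismatches = integer(0)),
                n_unmapped = length(reads), n_ambiguous = 0L))
  cand <- do.call(rbind, cand)
  # drop anchors whose full read would run off the scaffold
  ref_len <- Biostrings::width(reference)[match(cand$rname, names(reference))]
  cand <- cand[cand$pos + widths[cand$read] <= ref_len, , drop = FALSE]
  ref_chr <- as.character(reference)
  sub <- substring(ref_chr[cand$rname], cand$pos + 1L,
                   cand$pos + widths[cand$read])
  cand$mm <- .hamming(read_chr[cand$read], sub)
  cand <- cand[cand$mm <= max_mismatches, , drop = FALSE]
  n_amb <- 0L
  placed <- NULL
  if (nrow(cand) > 0L) {
    o <- order(cand$read, cand$mm)
    cand <- cand[o, , drop = FALSE]
    first <- !duplicated(cand$read)
    best <- cand[first, , drop = FALSE]
    # ambiguous = another candidate for the same read with the same distance
    nxt <- cand[!first, , drop = FALSE]
    tied <- unique(nxt$read[nxt$mm <= best$mm[match(nxt$read, best$read)]])
    n_amb <- length(tied)
    placed <- best[!best$read %in% tied, , drop = FALSE]
  }
  if (is.null(placed) || nrow(placed) == 0L) {
    placements <- data.frame(qname = character(0), rname = character(0),
                             pos = integer(0), mismatches = integer(0))
  } else {
    placements <- data.frame(qname = names(reads)[placed$read],
                             rname = placed$rname, pos = placed$pos,
                             mismatches = placed$mm, stringsAsFactors = FALSE)
  }
  list(placements = placements,
       n_unmapped = length(reads) - nrow(placements) - n_amb,
       n_ambiguous = n_amb)
}
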