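#' In-silico PCR over a template
#'
#' Scans both strands of the template for primer binding sites. A site primes
#' iff the 3'-terminal base matches exactly, at most one mismatch falls in the
#' 3'-terminal 5 nt, and at most `m_internal` mismatches fall elsewhere
#' (IUPAC ambiguity codes in the template count as mismatches). Every
#' plus-strand site paired with a minus-strand site is reported when the
#' spanned product — both primer footprints included — has
#' `0 < length <= max_product`.
#'
#' @param template character or [Biostrings::DNAString]; the molecule to
#'   amplify from.
#' @param primers a `multiplex_assay` or a list of `primer`s.
#' @param max_product maximum product length (bp), default 1000.
#' @param m_internal maximum mismatches outside the 3'-terminal 5 nt,
#'   default 3.
#' @param template_id label carried into the hits.
#' @return data.frame of amplicons: `template_id`, `start`, `end` (0-based
#'   half-open), `length`, `fwd_id`, `rev_id`, `mm_fwd`, `mm_rev`.
#' @export
in_silico_pcr <- function(template, primers, max_product = 1000L,
                          m_internal = 3L, template_id = "template") {
  if (inherits(primers, "multiplex_assay"))
    primers <- list(primers$b_forward, primers$control_forward,
                    primers$shared_reverse)
  if (inherits(primers, "primer")) primers <- list(primers)
  template <- as.character(template)
  tpl <- Biostrings::DNAString(template)
  fwd_sites <- list(); rev_sites <- list()
  for (p in primers) {
    seqp <- if (inherits(p, "primer")) p$sequence else as.character(p)
    idp <- if (inherits(p, "primer")) p$id else "primer"
    L <- nchar(seqp)
    # plus strand: primer as-is, 3' end rightmost
    s <- .candidate_starts(seqp, tpl, m_internal + 1L)
    for (st in s) {
      mm <- .site_mismatch_vector(seqp, template, st, L)
      if (.primes(mm, three_prime_left = FALSE, m_internal)) {
        fwd_sites[[length(fwd_sites) + 1L]] <-
          data.frame(id = idp, start = st, end = st + L, mm = sum(mm))
      }
    }
    # minus strand: reverse-complement lies on the plus strand, 3' end leftmost
    rc <- .revcomp(seqp)
    s <- .candidate_starts(rc, tpl, m_internal + 1L)
    for (st in s) {
      mm <- .site_mismatch_vector(rc, template, st, L)
      if (.primes(mm, three_prime_left = TRUE, m_internal)) {
        rev_sites[[length(rev_sites) + 1L]] <-
          data.frame(id = idp, start = st, end = st + L, mm = sum(mm))
      }
    }
  }
  empty <- data.frame(template_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      fwd_id = character(0), rev_id = character(0),
                      mm_fwd = integer(0), mm_rev = integer(0))
  if (length(fwd_sites) == 0L || length(rev_sites) == 0L) return(empty)
  fwd <- do.call(rbind, fwd_sites); rev <- do.call(rbind, rev_sites)
  out <- list()
  for (i in seq_len(nrow(fwd))) for (j in seq_len(nrow(rev))) {
    len <- rev$end[j] - fwd$start[i]
    if (len > 0L && len <= max_product)
      out[[length(out) + 1L]] <- data.frame(
        template_id = template_id, start = fwd$start[i], end = rev$end[j],
        length = len, fwd_id = fwd$id[i], rev_id = rev$id[j],
        mm_fwd = fwd$mm[i], mm_rev = rev$mm[j], stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

# 0-based starts where the oriented primer matches with <= max_mm mismatches
.candidate_starts <- function(oriented, tpl, max_mm) {
  m <- Biostrings::matchPattern(oriented, tpl, max.mismatch = max_mm,
                                with.indels = FALSE, fixed = TRUE)
  Biostrings::start(m) - 1L
}

# per-position mismatch indicator of the oriented primer at template start0
.site_mismatch_vector <- function(oriented, template, start0, L) {
  sub <- substring(template, start0 + 1L, start0 + L)
  charToRaw(oriented) != charToRaw(sub)
}

# priming rule: exact 3'-terminal base, <= 1 mismatch in 3'-terminal 5 nt,
# <= m_internal mismatches elsewhere
.primes <- function(mm, three_prime_left, m_internal) {
  L <- length(mm)
  if (three_prime_left) {
    term <- mm[seq_len(min(5L, L))]
    inner <- if (L > 5L) mm[6:L] else logical(0)
    if (mm[1L]) return(FALSE)
  } else {
    term <- mm[seq.int(max(1L, L - 4L), L)]
    inner <- if (L > 5L) mm[seq_len(L - 5L)] else logical(0)
    if (mm[L]) return(FALSE)
  }
  sum(term) <= 1L && sum(inner) <= m_internal
}

#' Call B presence/absence from in-silico PCR products
#'
#' Mirrors the gel readout of the multiplex: the control product (within
#' `length_tol` of the expected control length, primed by the control forward
#' and shared reverse) must appear for the reaction to be valid. With the
#' control present, the B-specific product (B forward + shared reverse) makes
#' the call `B_positive`; its absence makes `B_negative`. A missing control
#' product invalidates the reaction regardless of other bands.
#'
#' @param hits data.frame from [in_silico_pcr()] run with the assay's primers.
#' @param assay the `multiplex_assay`.
#' @param length_tol amplicon length tolerance (bp), default 5.
#' @return object of class `presence_call`: list with `value`
#'   (`"B_positive"`, `"B_negative"` or `"invalid"`) and `supporting`
#'   (the supporting amplicon rows).
#' @export
call_presence <- function(hits, assay, length_tol = 5L) {
  ctrl <- hits[hits$fwd_id == assay$control_forward$id &
               hits$rev_id == assay$shared_reverse$id &
               abs(hits$length - assay$expected_control_length) <= length_tol, ,
               drop = FALSE]
  bspec <- hits[hits$fwd_id == assay$b_forward$id &
                hits$rev_id == assay$shared_reverse$id &
                abs(hits$length - assay$expected_b_length) <= length_tol, ,
                drop = FALSE]
  value <- if (nrow(ctrl) == 0L) "invalid"
           else if (nrow(bspec) > 0L) "B_positive" else "B_negative"
  structure(list(value = value, supporting = rbind(ctrl, bspec)),
            class = "presence_call")
}

#' @export
print.presence_call <- function(x, ...) {
  cat("presence call:", x$value, "(", nrow(x$supporting), "supporting products )\n")
  invisible(x)
}
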