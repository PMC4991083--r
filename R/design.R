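#' Primer object
#'
#' @param id primer identifier; field naming follows the B/C + F/R scheme
#'   (suffix B = B-specific forward, C = control forward, R = shared reverse).
#' @param sequence 5'->3' sequence (A/C/G/T).
#' @param strand `"+"` (forward) or `"-"` (reverse).
#' @param template_start,template_end 0-based half-open footprint on the
#'   template/consensus coordinate system. The 3' end is `template_end - 1`
#'   for a plus-strand primer and `template_start` for a minus-strand one.
#' @param tm melting temperature (degrees C); computed if missing.
#' @return object of class `primer`.
#' @export
primer <- function(id, sequence, strand = "+", template_start = NA_integer_,
                   template_end = NA_integer_, tm = NULL) {
  sequence <- toupper(sequence)
  .check_dna_alphabet(sequence, sprintf("primer %s", id))
  len <- nchar(sequence)
  if (len < 18L || len > 40L)
    .abort("primer %s length %d outside 18-40 nt", id, len)
  if (!strand %in% c("+", "-")) .abort("strand must be + or -")
  if (is.null(tm)) tm <- melting_temp(sequence)
  gc <- sum(strsplit(sequence, "")[[1]] %in% c("G", "C")) / len
  structure(list(id = id, sequence = sequence, strand = strand,
                 template_start = as.integer(template_start),
                 template_end = as.integer(template_end),
                 end3 = if (strand == "+") as.integer(template_end) - 1L
                        else as.integer(template_start),
                 length = len, tm = tm, gc = gc),
            class = "primer")
}

.design_failure <- function(reason, details = NULL) {
  structure(list(ok = FALSE, reason = reason, details = details),
            class = "design_failure")
}

#' @export
print.design_failure <- function(x, ...) {
  cat("design failure:", x$reason, "\n")
  invisible(x)
}

#' Design the allele-specific (ARMS) forward primer
#'
#' The B-specific primer is a forward primer drawn from the B-derived contig
#' whose 3'-terminal base sits exactly on the diagnostic variant, so it
#' carries the B allele at its 3' end; a single 3'-terminal mismatch on a
#' non-B template abolishes priming. Among lengths in `length_range` whose
#' nearest-neighbor Tm falls inside `tm_range`, the one closest to the window
#' midpoint wins (shorter on ties).
#'
#' @param variant one row of [call_diagnostic_variants()] output (fields
#'   `contig_pos`, `b_base`, `position`).
#' @param contig the contig sequence the variant was called from.
#' @param length_range allowed primer lengths (nt), default 18-40.
#' @param tm_range target Tm window (degrees C), default 55-65.
#' @param id primer identifier.
#' @return a `primer` (template coordinates in the consensus frame via
#'   `variant$position`), or a `design_failure` listing the violated
#'   constraints.
#' @export
design_allele_specific_primer <- function(variant, contig,
                                          length_range = c(18L, 40L),
                                          tm_range = c(55, 65),
                                          id = "B-F") {
  contig <- as.character(contig)
  pos <- as.integer(variant$contig_pos)           # 0-based on contig
  if (substring(contig, pos + 1L, pos + 1L) != variant$b_base)
    .abort("contig base at the variant position is not the B allele")
  if (pos + 1L < length_range[1])
    return(.design_failure("insufficient contig sequence upstream of the variant"))
  lens <- seq(length_range[1], min(length_range[2], pos + 1L))
  cand <- substring(contig, pos + 2L - lens, pos + 1L)
  tms <- melting_temp(cand)
  ok <- tms >= tm_range[1] & tms <= tm_range[2]
  if (!any(ok))
    return(.design_failure("no primer length reaches the Tm window",
                           data.frame(length = lens, tm = tms)))
  mid <- mean(tm_range)
  pick <- which(ok)[order(abs(tms[ok] - mid), lens[ok])][1]
  tpl_pos <- as.integer(variant$position)
  primer(id, cand[pick], strand = "+",
         template_start = tpl_pos - lens[pick] + 1L,
         template_end = tpl_pos + 1L, tm = tms[pick])
}

#' Design the control forward / shared reverse primer pair
#'
#' Both primers lie entirely within conserved consensus columns so they bind B
#' and non-B templates alike. The control forward sits downstream of the
#' allele-specific site (at least `min_variant_offset` bp, which by
#' construction separates the control and B-specific products on a gel); the
#' shared reverse sits further downstream so one reverse primer closes both
#' products. The pair minimizing the combined distance of both Tms from the
#' window midpoint, then the deviation of the control product length from the
#' middle of `product_range`, wins.
#'
#' @param consensus a `consensus_alignment`.
#' @param variant_pos 0-based consensus position of the diagnostic variant.
#' @param length_range,tm_range primer constraints as in
#'   [design_allele_specific_primer()].
#' @param product_range allowed control-product length (bp), default 120-220.
#' @param min_variant_offset minimum distance from the variant to the control
#'   forward's 5' end (bp), default 45; separates the control and B products
#'   on the gel.
#' @param max_variant_offset maximum such distance (bp), default 150; keeps
#'   the B-specific product gel-sized.
#' @param search_start,search_end optional 0-based half-open window the
#'   primers must lie in (e.g. the interval covered by the B contig, so
#'   conservation is known on the B side too).
#' @param exclude 0-based consensus positions additionally treated as
#'   non-conserved (e.g. every contig/consensus mismatch, so control primers
#'   bind B and non-B templates identically).
#' @return list with `control_forward` and `shared_reverse` `primer`s, or a
#'   `design_failure`.
#' @export
design_control_pair <- function(consensus, variant_pos,
                                length_range = c(18L, 40L),
                                tm_range = c(55, 65),
                                product_range = c(120L, 220L),
                                min_variant_offset = 45L,
                                max_variant_offset = 150L,
                                search_start = 0L, search_end = NULL,
                                exclude = integer(0)) {
  cons <- consensus$consensus
  conserved <- consensus$conserved
  n <- nchar(cons)
  if (is.null(search_end)) search_end <- n
  keep <- exclude >= 0L & exclude < n
  conserved[exclude[keep] + 1L] <- FALSE
  runs <- .conserved_run_lengths(conserved)
  tm <- .tm_scan(cons)
  lens <- seq(length_range[1], length_range[2])
  cand <- list()
  for (L in lens) {
    # starts0 such that [s, s+L) is fully conserved and inside the window
    s0 <- which(conserved & runs$right + 1L >= L) - 1L
    s0 <- s0[s0 >= search_start & s0 + L <= search_end]
    if (length(s0) == 0L) next
    tms <- tm(s0, L)
    ok <- tms >= tm_range[1] & tms <= tm_range[2]
    if (any(ok))
      cand[[length(cand) + 1L]] <- data.frame(start = s0[ok], len = L,
                                              tm = tms[ok])
  }
  if (length(cand) == 0L)
    return(.design_failure("no conserved run hosts a primer in the Tm window"))
  cand <- do.call(rbind, cand)
  mid_tm <- mean(tm_range)
  cand$dtm <- abs(cand$tm - mid_tm)
  fwd <- cand[cand$start >= variant_pos + min_variant_offset &
              cand$start <= variant_pos + max_variant_offset, , drop = FALSE]
  if (nrow(fwd) == 0L)
    return(.design_failure("no conserved primer site downstream of the variant"))
  fwd <- fwd[order(fwd$dtm, fwd$start, fwd$len), , drop = FALSE]
  fwd <- head(fwd, 400L)
  rev <- cand
  rev$end <- rev$start + rev$len
  mid_prod <- mean(product_range)
  best <- NULL
  for (i in seq_len(nrow(fwd))) {
    fs <- fwd$start[i]; fe <- fs + fwd$len[i]
    r <- rev[rev$start >= fe &
             rev$end >= fs + product_range[1] &
             rev$end <= fs + product_range[2], , drop = FALSE]
    if (nrow(r) == 0L) next
    sc <- fwd$dtm[i] + r$dtm + abs((r$end - fs) - mid_prod) / 1000
    j <- order(sc, r$start, r$len)[1]
    if (is.null(best) || sc[j] < best$score)
      best <- list(score = sc[j], f = fwd[i, ], r = r[j, ])
  }
  if (is.null(best))
    return(.design_failure("no forward/reverse pair yields a product in range"))
  f <- best$f; r <- best$r
  list(control_forward = primer("C-F",
         substring(cons, f$start + 1L, f$start + f$len), strand = "+",
         template_start = f$start, template_end = f$start + f$len, tm = f$tm),
       shared_reverse = primer("R",
         .revcomp(substring(cons, r$start + 1L, r$start + r$len)),
         strand = "-", template_start = r$start,
         template_end = r$start + r$len, tm = r$tm))
}

# longest x such that the 3'-terminal x nt of a are reverse-complementary to
# the 3'-terminal x nt of b
.cross_dimer_run <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  run <- 0L
  for (x in seq_len(min(la, lb))) {
    if (substring(a, la - x + 1L, la) == .revcomp(substring(b, lb - x + 1L, lb)))
      run <- x
  }
  run
}

#' Assemble and vet the three-primer multiplex assay
#'
#' Computes the expected control and B-specific product lengths from the
#' primer footprints and checks gel resolvability (`|L_B - L_C| >= delta_gel`),
#' the pairwise Tm span, and 3' cross-complementarity between every primer
#' pair (a reverse-complementary 3' run of `dimer_max_run` nt or more is
#' rejected as a primer-dimer risk). The B-specific forward must carry its
#' anchoring variant's B allele at the 3' terminus.
#'
#' @param b_forward,control_forward,shared_reverse `primer`s on one template
#'   coordinate system.
#' @param delta_gel minimum product-size gap resolvable on the gel (bp),
#'   default 40.
#' @param tm_span_max maximum pairwise Tm difference (degrees C), default 5.
#' @param dimer_max_run 3' cross-complementarity runs of at least this many
#'   nt are rejected, default 5.
#' @return object of class `multiplex_assay` (fields `b_forward`,
#'   `control_forward`, `shared_reverse`, `expected_control_length`,
#'   `expected_b_length`, `constraint_report`) or a `design_failure` naming
#'   the violated constraint.
#' @export
assemble_multiplex <- function(b_forward, control_forward, shared_reverse,
                               delta_gel = 40L, tm_span_max = 5,
                               dimer_max_run = 5L) {
  for (p in list(b_forward, control_forward, shared_reverse))
    if (!inherits(p, "primer")) .abort("all three inputs must be primers")
  if (shared_reverse$strand != "-" || b_forward$strand != "+" ||
      control_forward$strand != "+")
    .abort("expected two forward primers and one reverse primer")
  l_c <- shared_reverse$template_end - control_forward$template_start
  l_b <- shared_reverse$template_end - b_forward$template_start
  tms <- c(b_forward$tm, control_forward$tm, shared_reverse$tm)
  span <- max(tms) - min(tms)
  prs <- list(c("b_forward", "control_forward"),
              c("b_forward", "shared_reverse"),
              c("control_forward", "shared_reverse"))
  seqs <- list(b_forward = b_forward$sequence,
               control_forward = control_forward$sequence,
               shared_reverse = shared_reverse$sequence)
  dimers <- vapply(prs, function(p) .cross_dimer_run(seqs[[p[1]]], seqs[[p[2]]]), 1L)
  report <- list(expected_control_length = l_c, expected_b_length = l_b,
                 size_gap = abs(l_b - l_c), tm_span = span,
                 dimer_runs = stats::setNames(dimers, vapply(prs, paste,
                                                             "", collapse = ":")))
  if (abs(l_b - l_c) < delta_gel)
    return(.design_failure(sprintf(
      "product sizes %d and %d are gel-unresolvable (gap < %d bp)",
      l_c, l_b, delta_gel), report))
  if (span > tm_span_max)
    return(.design_failure(sprintf("Tm span %.1f exceeds %.1f", span,
                                   tm_span_max), report))
  if (any(dimers >= dimer_max_run))
    return(.design_failure("3' cross-complementarity (primer-dimer risk)",
                           report))
  structure(list(b_forward = b_forward, control_forward = control_forward,
                 shared_reverse = shared_reverse,
                 expected_control_length = l_c, expected_b_length = l_b,
                 constraint_report = report),
            class = "multiplex_assay")
}
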