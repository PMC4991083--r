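#' Windowed read-depth profile of one sample
#'
#' Counts primary mapped reads into fixed, non-overlapping windows by the
#' leftmost-aligned-base rule: each read increments exactly one window, the
#' one containing its leftmost aligned base. The rule conserves reads (window
#' counts sum to the library size) and is order-independent.
#'
#' @param alignments either a data.frame of placements with columns `rname`
#'   and `pos` (0-based leftmost base), as returned by [map_reads_exact()]
#'   or [read_alignments()], or a path to a SAM/BAM file (unmapped, secondary
#'   and duplicate records are excluded on read).
#' @param scaffold_lengths named integer vector of scaffold lengths (bp).
#' @param window_size window width in bp (>= 50).
#' @param sample_id,genotype labels carried on the profile.
#' @param min_mapq MAPQ filter applied when `alignments` is a file path.
#' @return object of class `depth_profile`: list with `sample_id`, `genotype`,
#'   `window_size`, `counts` (named list of integer vectors, one per
#'   scaffold), `scaffold_lengths`, `library_size`.
#' @export
window_depth <- function(alignments, scaffold_lengths, window_size = 1000L,
                         sample_id = "sample", genotype = NA_character_,
                         min_mapq = 0L) {
  window_size <- as.integer(window_size)
  if (window_size < 50L) .abort("window_size must be >= 50 bp")
  if (is.character(alignments) && length(alignments) == 1L) {
    aln <- read_alignments(alignments, min_mapq = min_mapq)
    if (missing(scaffold_lengths)) scaffold_lengths <- attr(aln, "scaffold_lengths")
    alignments <- aln
  }
  if (inherits(alignments, "list") && !is.null(alignments$placements))
    alignments <- alignments$placements
  if (is.null(names(scaffold_lengths)))
    .abort("scaffold_lengths must be a named vector")
  bad <- setdiff(unique(alignments$rname), names(scaffold_lengths))
  if (length(bad) > 0L)
    .abort("alignment reference name absent from index: %s", bad[1])
  counts <- lapply(names(scaffold_lengths), function(sc) {
    n_win <- as.integer(ceiling(scaffold_lengths[[sc]] / window_size))
    pos <- alignments$pos[alignments$rname == sc]
    if (length(pos) == 0L) return(integer(n_win))
    tabulate(pos %/% window_size + 1L, nbins = n_win)
  })
  names(counts) <- names(scaffold_lengths)
  structure(list(sample_id = sample_id, genotype = genotype,
                 window_size = window_size, counts = counts,
                 scaffold_lengths = scaffold_lengths,
                 library_size = nrow(alignments)),
            class = "depth_profile")
}

#' Library-size normalization of a depth profile
#'
#' Scales window counts to reads-per-million so 0B/1B/2B libraries of very
#' different sizes become comparable: `nd = count * 1e6 / library_size`.
#'
#' @param profile a `depth_profile`.
#' @return named list of numeric vectors (normalized depth per window).
#' @export
normalize_depth <- function(profile) {
  if (profile$library_size <= 0L) .abort("library_size must be > 0")
  lapply(profile$counts, function(x) x * 1e6 / profile$library_size)
}

#' Per-window 1B/0B and 2B/0B coverage-ratio track
#'
#' Normalizes each profile to reads-per-million and forms, per window,
#' `r1 = (nd1 + alpha) / (nd0 + alpha)` and `r2 = (nd2 + alpha) / (nd0 +
#' alpha)`. The pseudocount `alpha > 0` keeps ratios finite on empty windows
#' (a window empty in all three samples has r1 = r2 = 1).
#'
#' @param p0,p1,p2 `depth_profile`s of the 0B, 1B and 2B samples; must share
#'   window size and scaffold set.
#' @param alpha pseudocount (> 0), default 0.5.
#' @return object of class `ratio_track`: data.frame with columns `scaffold`,
#'   `window`, `start`, `end`, `nd0`, `nd1`, `nd2`, `r1`, `r2`; attributes
#'   `window_size`, `alpha`, `scaffold_lengths`.
#' @export
ratio_track <- function(p0, p1, p2, alpha = 0.5) {
  if (alpha <= 0) .abort("alpha must be > 0")
  profs <- list(p0, p1, p2)
  ws <- vapply(profs, function(p) p$window_size, 1L)
  if (length(unique(ws)) != 1L) .abort("profiles have different window sizes")
  scs <- lapply(profs, function(p) names(p$counts))
  if (!all(vapply(scs[-1], identical, TRUE, scs[[1]])))
    .abort("profiles cover different scaffold sets")
  nd <- lapply(profs, normalize_depth)
  rows <- lapply(scs[[1]], function(sc) {
    n <- length(nd[[1]][[sc]])
    if (length(nd[[2]][[sc]]) != n || length(nd[[3]][[sc]]) != n)
      .abort("window counts differ on scaffold %s", sc)
    w <- ws[1]
    data.frame(scaffold = sc, window = seq_len(n) - 1L,
               start = (seq_len(n) - 1L) * w,
               end = pmin(seq_len(n) * w, p0$scaffold_lengths[[sc]]),
               nd0 = nd[[1]][[sc]], nd1 = nd[[2]][[sc]], nd2 = nd[[3]][[sc]],
               stringsAsFactors = FALSE)
  })
  track <- do.call(rbind, rows)
  track$r1 <- (track$nd1 + alpha) / (track$nd0 + alpha)
  track$r2 <- (track$nd2 + alpha) / (track$nd0 + alpha)
  structure(track, window_size = ws[1], alpha = alpha,
            scaffold_lengths = p0$scaffold_lengths,
            class = c("ratio_track", "data.frame"))
}

#' Detect candidate B-enriched blocks from a coverage-ratio track
#'
#' A window passes when both `r1 >= theta` and `r2 >= theta` — enrichment must
#' show in every B-positive sample, encoding "exclusive to B genomes".
#' Passing windows separated by at most `max_gap` failing windows are merged
#' into one block; a block is kept when it contains at least `min_windows`
#' passing windows. Block coordinates are window-aligned (the final window is
#' clipped to the scaffold end).
#'
#' Per block the summary covers every window in the merged span:
#' `mean_r1`, `mean_r2`, the within-block coefficient of variation of r2, and
#' the dose consistency `D = |(mean_r2 - 1) - 2 (mean_r1 - 1)|`, which is ~0
#' when enrichment follows a linear gene-dose model (one B adds c copies, two
#' Bs add 2c).
#'
#' @param track a `ratio_track`.
#' @param theta ratio threshold (> 1), default 1.5.
#' @param min_windows minimum passing windows per block, default 3.
#' @param max_gap maximum run of sub-threshold windows bridged inside a
#'   block, default 1.
#' @return data.frame of blocks: `scaffold`, `start`, `end`, `n_windows`,
#'   `mean_r1`, `mean_r2`, `cv_r2`, `dose_consistency`.
#' @export
detect_blocks <- function(track, theta = 1.5, min_windows = 3L, max_gap = 1L) {
  if (theta <= 1) .abort("theta must be > 1")
  out <- list()
  for (sc in unique(track$scaffold)) {
    tr <- track[track$scaffold == sc, , drop = FALSE]
    tr <- tr[order(tr$window), , drop = FALSE]
    pass <- which(tr$r1 >= theta & tr$r2 >= theta)
    if (length(pass) == 0L) next
    grp <- cumsum(c(1L, diff(pass) > max_gap + 1L))
    for (g in split(pass, grp)) {
      if (length(g) < min_windows) next
      span <- seq(min(g), max(g))
      r1 <- tr$r1[span]; r2 <- tr$r2[span]
      out[[length(out) + 1L]] <- data.frame(
        scaffold = sc,
        start = tr$start[min(g)],
        end = tr$end[max(g)],
        n_windows = length(span),
        mean_r1 = mean(r1), mean_r2 = mean(r2),
        cv_r2 = if (length(span) > 1L) sd(r2) / mean(r2) else 0,
        dose_consistency = abs((mean(r2) - 1) - 2 * (mean(r1) - 1)),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), n_windows = integer(0),
                      mean_r1 = numeric(0), mean_r2 = numeric(0),
                      cv_r2 = numeric(0), dose_consistency = numeric(0)))
  do.call(rbind, out)
}

#' Rank candidate blocks for qPCR follow-up
#'
#' Stable sort by ascending dose consistency, then ascending within-block
#' coefficient of variation of r2, then descending mean r2; remaining ties
#' break by genomic coordinate. Blocks whose enrichment tracks the linear
#' gene-dose model with a stable signal rank first — the analogue of
#' discarding regions with erratic qPCR signal.
#'
#' @param blocks data.frame from [detect_blocks()] (>= 1 row).
#' @return the same data.frame, reordered.
#' @export
rank_blocks <- function(blocks) {
  if (nrow(blocks) < 1L) .abort("rank_blocks needs at least one block")
  o <- order(blocks$dose_consistency, blocks$cv_r2, -blocks$mean_r2,
             blocks$scaffold, blocks$start)
  blocks[o, , drop = FALSE]
}

#' Size of a genomic block
#'
#' Intervals are 0-based half-open, so size is simply `end - start`.
#'
#' @param block data.frame (or list) with `start` and `end`.
#' @return integer vector of sizes in bp.
#' @export
block_size <- function(block) {
  if (any(block$end <= block$start)) .abort("blocks must have end > start")
  as.integer(block$end - block$start)
}
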