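#' Study-design parameters for a synthetic 0B/1B/2B cohort
#'
#' Bundles every parameter of the simulated world: reference scaffolds, the
#' blocks of the A complement that the B chromosome has duplicated to high
#' copy number, the density of B-diagnostic substitutions inside those blocks,
#' the sequencing model (single-end read length, fold-coverage per haploid
#' genome copy, per-base substitution error), and the qPCR Ct model (baseline
#' cycle and Gaussian replicate noise).
#'
#' Coordinates are 0-based, half-open throughout the package; an interval's
#' size is `end - start`.
#'
#' @param seed single global integer seed; every stage derives its own stream
#'   from it (see [derive_seed()]).
#' @param scaffold_lengths integer vector of scaffold lengths in bp,
#'   optionally named.
#' @param b_blocks data.frame with columns `scaffold`, `start`, `end`
#'   (0-based half-open on the reference) and `copies_on_b` (integer >= 1):
#'   the A-complement blocks the B carries, and at what copy number.
#' @param snv_rate_in_blocks per-base probability that a block position
#'   carries a B-diagnostic substitution (drawn once per site, shared by all
#'   copies on the B).
#' @param read_length single-end read length in bp.
#' @param depth_per_haploid_copy fold-coverage contributed by each haploid
#'   copy of each template.
#' @param read_error_rate per-base substitution error rate of simulated reads.
#' @param ct_baseline baseline cycle C0 of the Ct model: a template present at
#'   k copies crosses threshold at `C0 - log2(k)` cycles.
#' @param ct_noise_sd Gaussian standard deviation (cycles) added independently
#'   to every Ct replicate.
#' @param a_complement_copies copies of each template region in the A
#'   complement; the default 2 models an ordinary diploid locus.
#' @return an object of class `truth_spec`.
#' @export
truth_spec <- function(seed = 1L,
                       scaffold_lengths = c(scaffold_1 = 20000L,
                                            scaffold_2 = 15000L),
                       b_blocks = data.frame(scaffold = "scaffold_1",
                                             start = 5000L, end = 10000L,
                                             copies_on_b = 10L),
                       snv_rate_in_blocks = 0.01,
                       read_length = 100L,
                       depth_per_haploid_copy = 20,
                       read_error_rate = 0.001,
                       ct_baseline = 30,
                       ct_noise_sd = 0.2,
                       a_complement_copies = 2L) {
  nm <- names(scaffold_lengths)
  scaffold_lengths <- as.integer(scaffold_lengths)
  names(scaffold_lengths) <- nm
  if (any(scaffold_lengths < 1L)) .abort("scaffold lengths must be >= 1")
  if (is.null(names(scaffold_lengths)) || any(names(scaffold_lengths) == ""))
    names(scaffold_lengths) <- sprintf("scaffold_%d", seq_along(scaffold_lengths))
  need <- c("scaffold", "start", "end", "copies_on_b")
  if (!all(need %in% names(b_blocks)))
    .abort("b_blocks needs columns %s", paste(need, collapse = ", "))
  if (any(b_blocks$copies_on_b < 1L)) .abort("copies_on_b must be >= 1")
  if (any(b_blocks$end <= b_blocks$start)) .abort("b_blocks must have end > start")
  for (r in seq_len(nrow(b_blocks))) {
    sc <- b_blocks$scaffold[r]
    if (!sc %in% names(scaffold_lengths))
      .abort("block scaffold %s not among scaffolds", sc)
    if (b_blocks$start[r] < 0L || b_blocks$end[r] > scaffold_lengths[[sc]])
      .abort("block %d outside scaffold %s bounds", r, sc)
  }
  for (p in c(snv_rate_in_blocks, read_error_rate))
    if (p < 0 || p > 1) .abort("rates must lie in [0, 1]")
  if (depth_per_haploid_copy <= 0) .abort("depth_per_haploid_copy must be > 0")
  if (read_length < 20L) .abort("read_length must be >= 20")
  if (ct_noise_sd < 0) .abort("ct_noise_sd must be >= 0")
  if (a_complement_copies < 1L) .abort("a_complement_copies must be >= 1")
  structure(list(seed = as.integer(seed),
                 scaffold_lengths = scaffold_lengths,
                 b_blocks = b_blocks,
                 snv_rate_in_blocks = snv_rate_in_blocks,
                 read_length = as.integer(read_length),
                 depth_per_haploid_copy = depth_per_haploid_copy,
                 read_error_rate = read_error_rate,
                 ct_baseline = ct_baseline,
                 ct_noise_sd = ct_noise_sd,
                 a_complement_copies = as.integer(a_complement_copies)),
            class = "truth_spec")
}

#' Generate a random reference genome
#'
#' Scaffolds are i.i.d. uniform A/C/G/T; the same seed always yields the same
#' sequences.
#'
#' @param seed integer seed.
#' @param scaffold_lengths integer vector of lengths (bp), optionally named.
#' @return a [Biostrings::DNAStringSet] with one record per length.
#' @export
make_reference <- function(seed, scaffold_lengths) {
  nm <- names(scaffold_lengths)
  scaffold_lengths <- as.integer(scaffold_lengths)
  names(scaffold_lengths) <- nm
  if (length(scaffold_lengths) == 0L || any(scaffold_lengths < 1L))
    .abort("scaffold lengths must be positive")
  if (is.null(names(scaffold_lengths)) || any(names(scaffold_lengths) == ""))
    names(scaffold_lengths) <- sprintf("scaffold_%d", seq_along(scaffold_lengths))
  seqs <- .with_stage_seed(seed, "reference", {
    vapply(scaffold_lengths, .random_dna, "")
  })
  ref <- Biostrings::DNAStringSet(seqs)
  names(ref) <- names(scaffold_lengths)
  ref
}

#' Build the B-chromosome sequence from duplicated A-complement blocks
#'
#' The B sequence is the concatenation of each source block repeated
#' `copies_on_b` times. Diagnostic substitutions are drawn once per block
#' position at `snv_rate_in_blocks` (the substituted base never equals the
#' reference base) and planted identically in every copy, so they are
#' B-diagnostic: present on all B copies, absent from the A complement.
#'
#' @param reference a [Biostrings::DNAStringSet] from [make_reference()].
#' @param spec a [truth_spec()].
#' @return an object of class `b_genome`: list with `b_sequence`
#'   (a [Biostrings::DNAString]), `truth_blocks` (the block table),
#'   `truth_variants` (data.frame scaffold, pos, ref, alt; 0-based pos on the
#'   reference) and `copy_map` (data.frame mapping each copy's interval on the
#'   B sequence back to its source interval).
#' @export
make_b_sequence <- function(reference, spec) {
  blocks <- spec$b_blocks
  for (sc in unique(blocks$scaffold)) {
    bl <- blocks[blocks$scaffold == sc, , drop = FALSE]
    bl <- bl[order(bl$start), , drop = FALSE]
    if (nrow(bl) > 1L && any(bl$start[-1L] < bl$end[-nrow(bl)]))
      .abort("overlapping b_blocks on scaffold %s", sc)
    if (!sc %in% names(reference)) .abort("scaffold %s absent from reference", sc)
  }
  .with_stage_seed(spec$seed, "b_sequence", {
    variants <- list(); pieces <- character(0); copy_map <- list()
    b_off <- 0L
    for (r in seq_len(nrow(blocks))) {
      sc <- blocks$scaffold[r]
      start <- blocks$start[r]; end <- blocks$end[r]
      copies <- blocks$copies_on_b[r]
      src <- as.character(Biostrings::subseq(reference[[sc]], start + 1L, end))
      len <- end - start
      hit <- which(runif(len) < spec$snv_rate_in_blocks)
      chars <- strsplit(src, "")[[1]]
      if (length(hit) > 0L) {
        alt <- .mutate_bases(chars[hit])
        variants[[length(variants) + 1L]] <- data.frame(
          scaffold = sc, pos = start + hit - 1L,
          ref = chars[hit], alt = alt, stringsAsFactors = FALSE)
        chars[hit] <- alt
      }
      mutated <- paste(chars, collapse = "")
      for (cp in seq_len(copies)) {
        pieces <- c(pieces, mutated)
        copy_map[[length(copy_map) + 1L]] <- data.frame(
          block = r, copy = cp, scaffold = sc,
          src_start = start, src_end = end,
          b_start = b_off, b_end = b_off + len, stringsAsFactors = FALSE)
        b_off <- b_off + len
      }
    }
    truth_variants <- if (length(variants)) do.call(rbind, variants) else
      data.frame(scaffold = character(0), pos = integer(0),
                 ref = character(0), alt = character(0))
    structure(list(b_sequence = Biostrings::DNAString(paste(pieces, collapse = "")),
                   truth_blocks = blocks,
                   truth_variants = truth_variants,
                   copy_map = do.call(rbind, copy_map)),
              class = "b_genome")
  })
}

.N_B <- c("0B" = 0L, "1B" = 1L, "2B" = 2L)

#' Simulate a single-end read set for one genotype
#'
#' The template pool holds `a_complement_copies` copies of every reference
#' scaffold plus `nB` copies of the B sequence (`nB` = 0, 1, 2 by genotype).
#' The total read count is `round(pool_bases * depth_per_haploid_copy /
#' read_length)`, exactly; reads start uniformly within each template and are
#' drawn from templates proportionally to `copies x length`, so coverage over
#' B-derived blocks scales with the B count. Per-base substitution errors are
#' applied at `read_error_rate`.
#'
#' @param reference reference [Biostrings::DNAStringSet].
#' @param b_genome result of [make_b_sequence()] (ignored for genotype "0B"
#'   pool weighting only in the sense that nB = 0).
#' @param genotype one of `"0B"`, `"1B"`, `"2B"`.
#' @param spec a [truth_spec()].
#' @param seed optional override seed; default derives one from
#'   `spec$seed` and the genotype label.
#' @return object of class `read_set`: list with `reads` (named
#'   [Biostrings::DNAStringSet]), `qualities` (constant Phred+33 "I"),
#'   `truth` (data.frame qname, template, start) and `genotype`.
#' @export
simulate_reads <- function(reference, b_genome, genotype, spec, seed = NULL) {
  if (!genotype %in% names(.N_B)) .abort("genotype must be one of 0B, 1B, 2B")
  nb <- .N_B[[genotype]]
  L <- spec$read_length
  templates <- c(as.list(as.character(reference)),
                 list(B = as.character(b_genome$b_sequence)))
  names(templates) <- c(names(reference), "B")
  copies <- c(rep(spec$a_complement_copies, length(reference)), nb)
  keep <- copies > 0L
  templates <- templates[keep]; copies <- copies[keep]
  lens <- vapply(templates, nchar, 1L)
  if (any(lens < L)) .abort("read_length exceeds a template length")
  pool_bases <- sum(as.numeric(copies) * lens)
  n_reads <- as.integer(round(pool_bases * spec$depth_per_haploid_copy / L))
  if (is.null(seed)) seed <- derive_seed(spec$seed, paste0("reads_", genotype))
  withr::with_seed(as.integer(seed), {
    t_idx <- sample.int(length(templates), n_reads, replace = TRUE,
                        prob = as.numeric(copies) * lens)
    starts <- integer(n_reads)
    for (t in seq_along(templates)) {
      sel <- t_idx == t
      starts[sel] <- sample.int(lens[t] - L + 1L, sum(sel), replace = TRUE) - 1L
    }
    seqs <- substring(unlist(templates)[t_idx], starts + 1L, starts + L)
    if (spec$read_error_rate > 0) {
      n_err <- rbinom(n_reads, L, spec$read_error_rate)
      for (i in which(n_err > 0L)) {
        ch <- strsplit(seqs[i], "")[[1]]
        p <- sample.int(L, n_err[i])
        ch[p] <- .mutate_bases(ch[p])
        seqs[i] <- paste(ch, collapse = "")
      }
    }
    qname <- sprintf("r%07d|%s|%d", seq_len(n_reads), names(templates)[t_idx], starts)
    reads <- Biostrings::DNAStringSet(seqs)
    names(reads) <- qname
    structure(list(reads = reads,
                   qualities = strrep("I", L),
                   truth = data.frame(qname = qname,
                                      template = names(templates)[t_idx],
                                      start = starts, stringsAsFactors = FALSE),
                   genotype = genotype),
              class = "read_set")
  })
}

#' Simulate microdissection-style B contigs
#'
#' Contigs are exact substrings of the B sequence with lengths drawn from a
#' truncated normal (default mean 372 bp, sd 100 bp, truncated to
#' `[100, 1000]`, echoing the typical assembly size of microdissected-
#' chromosome sequencing).
#'
#' @param b_sequence [Biostrings::DNAString] (or a `b_genome`).
#' @param n number of contigs (>= 1).
#' @param mean_length,sd_length,min_length,max_length truncated-normal length
#'   distribution parameters (bp).
#' @param fixed_length if given, all contigs get exactly this length.
#' @param seed integer seed.
#' @return named [Biostrings::DNAStringSet] with `mcols()` columns `b_start`,
#'   `b_end` (0-based half-open origin on the B sequence).
#' @export
simulate_b_contigs <- function(b_sequence, n, mean_length = 372,
                               sd_length = 100, min_length = 100,
                               max_length = 1000, fixed_length = NULL,
                               seed = 1L) {
  if (inherits(b_sequence, "b_genome")) b_sequence <- b_sequence$b_sequence
  if (length(n) != 1L || n < 1L) .abort("n must be >= 1")
  blen <- length(b_sequence)
  withr::with_seed(derive_seed(seed, "contigs"), {
    if (!is.null(fixed_length)) {
      lens <- rep(as.integer(fixed_length), n)
    } else {
      lens <- integer(0)
      while (length(lens) < n) {
        cand <- as.integer(round(rnorm(n, mean_length, sd_length)))
        lens <- c(lens, cand[cand >= min_length & cand <= max_length])
      }
      lens <- lens[seq_len(n)]
    }
    lens <- pmin(lens, blen)
    starts <- vapply(lens, function(l) sample.int(blen - l + 1L, 1L) - 1L, 1L)
    seqs <- Biostrings::DNAStringSet(vapply(seq_len(n), function(i)
      as.character(Biostrings::subseq(b_sequence, starts[i] + 1L,
                                      starts[i] + lens[i])), ""))
    names(seqs) <- sprintf("contig_%05d", seq_len(n))
    S4Vectors::mcols(seqs) <- S4Vectors::DataFrame(b_start = starts,
                                                   b_end = starts + lens)
    seqs
  })
}

#' Simulate a triplicate qPCR Ct table
#'
#' Inverse model of gene-dose-ratio quantification: a sample of genotype nB
#' carries `a + nB * c` copies of the marker region (a in the A complement,
#' c added per B) and `a_ref` copies of the reference gene (HPRT), and a
#' template at k copies crosses threshold at `C0 - log2(k)` cycles, plus
#' independent Gaussian noise per replicate. Doubling the template therefore
#' lowers Ct by exactly one cycle when noise is zero.
#'
#' @param genotypes named character vector, `sample_id -> "0B"/"1B"/"2B"`.
#' @param a marker copies in the A complement (>= 1).
#' @param c_per_b marker copies added per B chromosome (>= 1).
#' @param a_ref copies of the HPRT reference locus (constant across
#'   genotypes).
#' @param c0 baseline cycle C0.
#' @param noise_sd Gaussian Ct noise (cycles), >= 0.
#' @param replicates replicates per (sample, assay); default 3.
#' @param seed integer seed.
#' @param known logical vector (recycled): whether each sample's genotype is
#'   recorded in the table (calibration controls) or withheld (unknowns).
#' @return data.frame with columns `sample_id`, `genotype` (NA where
#'   withheld), `assay` (`"target"` or `"HPRT"`), `replicate`, `ct`.
#' @export
simulate_ct <- function(genotypes, a = 2, c_per_b = 100, a_ref = 2,
                        c0 = 30, noise_sd = 0.2, replicates = 3L,
                        seed = 1L, known = TRUE) {
  if (a < 1 || c_per_b < 1) .abort("a and c_per_b must be >= 1")
  if (noise_sd < 0) .abort("noise_sd must be >= 0")
  if (is.null(names(genotypes)) || any(names(genotypes) == ""))
    .abort("genotypes must be a named vector (sample_id -> genotype)")
  if (!all(genotypes %in% names(.N_B))) .abort("genotypes must be 0B/1B/2B")
  known <- rep_len(known, length(genotypes))
  withr::with_seed(derive_seed(seed, "ct"), {
    rows <- lapply(seq_along(genotypes), function(i) {
      nb <- .N_B[[genotypes[[i]]]]
      tgt <- c0 - log2(a + nb * c_per_b) + rnorm(replicates, 0, noise_sd)
      ref <- c0 - log2(a_ref) + rnorm(replicates, 0, noise_sd)
      data.frame(sample_id = names(genotypes)[i],
                 genotype = if (known[i]) genotypes[[i]] else NA_character_,
                 assay = rep(c("target", "HPRT"), each = replicates),
                 replicate = rep(seq_len(replicates), 2L),
                 ct = c(tgt, ref), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Simulate an ortholog panel around one genomic region
#'
#' Produces `n_species` equal-length ortholog sequences of a region: the
#' region itself plus copies carrying independent substitutions at the given
#' divergence. Substitution-only, so the panel is pre-aligned column-for-
#' column and can feed [build_consensus()] directly.
#'
#' @param region_seq character or [Biostrings::DNAString].
#' @param n_species panel size (>= 2).
#' @param divergence per-base substitution probability per non-focal species.
#' @param seed integer seed.
#' @return [Biostrings::DNAStringSet] of `n_species` aligned sequences.
#' @export
simulate_reference_panel <- function(region_seq, n_species = 3,
                                     divergence = 0.02, seed = 1L) {
  if (n_species < 2) .abort("n_species must be >= 2")
  region_seq <- as.character(region_seq)
  withr::with_seed(derive_seed(seed, "panel"), {
    seqs <- c(region_seq, vapply(seq_len(n_species - 1L), function(i) {
      ch <- strsplit(region_seq, "")[[1]]
      hit <- which(runif(length(ch)) < divergence)
      if (length(hit)) ch[hit] <- .mutate_bases(ch[hit])
      paste(ch, collapse = "")
    }, ""))
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- sprintf("species_%d", seq_len(n_species))
    out
  })
}
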