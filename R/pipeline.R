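#' Pipeline configuration
#'
#' One versioned, serializable object holds every stage parameter and the
#' global seed. Defaults equal the documented defaults of the stage functions.
#' Unknown parameter names are rejected (fail-fast), and a config round-trips
#' through YAML unchanged.
#'
#' @param seed global integer seed.
#' @param ... overrides of any parameter listed in the default config (see
#'   the fields of the returned object).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    schema_version = 1L,
    seed = as.integer(seed),
    # synthetic world
    scaffold_lengths = c(scaffold_1 = 20000L, scaffold_2 = 15000L),
    b_block_scaffold = "scaffold_1",
    b_block_start = 5000L, b_block_end = 10000L, b_block_copies = 10L,
    snv_rate_in_blocks = 0.01,
    read_length = 100L, depth_per_haploid_copy = 20,
    read_error_rate = 0.001, a_complement_copies = 2L,
    n_contigs = 40L,
    panel_species = 3L, panel_divergence = 0.02,
    # coverage scan
    window_size = 1000L, alpha = 0.5, theta = 1.5,
    min_windows = 3L, max_gap = 1L, min_mapq = 0L,
    mapper_k = 31L, mapper_max_mismatches = 2L,
    # marker design
    min_flank = 20L, tm_lo = 55, tm_hi = 65,
    primer_len_lo = 18L, primer_len_hi = 40L,
    delta_gel = 40L, tm_span_max = 5, dimer_max_run = 5L,
    control_product_lo = 120L, control_product_hi = 220L,
    max_product = 1000L, m_internal = 3L, presence_length_tol = 5L,
    # qPCR dose
    ct_baseline = 30, ct_noise_sd = 0.2,
    ct_a = 2, ct_c_per_b = 100, ct_a_ref = 2, ct_replicates = 3L,
    n_controls_per_class = 3L, n_unknown = 9L,
    sd_flag = 0.5, epsilon = 0.25,
    verbose = FALSE)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L)
    .abort("unknown config parameter(s): %s", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  .validate_config(structure(cfg, class = "pipeline_config"))
}

.validate_config <- function(cfg) {
  if (cfg$theta <= 1) .abort("theta must be > 1")
  if (cfg$alpha <= 0) .abort("alpha must be > 0")
  if (cfg$window_size < 50L) .abort("window_size must be >= 50")
  if (cfg$tm_lo >= cfg$tm_hi) .abort("Tm window is empty")
  if (cfg$primer_len_lo < 18L || cfg$primer_len_hi > 40L)
    .abort("primer lengths must stay within 18-40 nt")
  if (cfg$ct_noise_sd < 0) .abort("ct_noise_sd must be >= 0")
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) .abort("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$schema_version) || raw$schema_version != 1L)
    .abort("unsupported config schema_version (expected 1)")
  raw$schema_version <- NULL
  sl <- raw$scaffold_lengths
  if (!is.null(sl)) raw$scaffold_lengths <- unlist(sl)
  seed <- if (is.null(raw$seed)) 1L else raw$seed
  raw$seed <- NULL
  do.call(pipeline_config, c(list(seed = seed), raw))
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  raw <- unclass(cfg)
  # YAML keeps names on maps but not on atomic sequences
  raw$scaffold_lengths <- as.list(raw$scaffold_lengths)
  yaml::write_yaml(raw, path)
  invisible(path)
}

# truth_spec from a pipeline config
.spec_from_config <- function(cfg) {
  truth_spec(seed = cfg$seed,
             scaffold_lengths = cfg$scaffold_lengths,
             b_blocks = data.frame(scaffold = cfg$b_block_scaffold,
                                   start = cfg$b_block_start,
                                   end = cfg$b_block_end,
                                   copies_on_b = cfg$b_block_copies),
             snv_rate_in_blocks = cfg$snv_rate_in_blocks,
             read_length = cfg$read_length,
             depth_per_haploid_copy = cfg$depth_per_haploid_copy,
             read_error_rate = cfg$read_error_rate,
             ct_baseline = cfg$ct_baseline,
             ct_noise_sd = cfg$ct_noise_sd,
             a_complement_copies = cfg$a_complement_copies)
}

#' Simulate a full synthetic cohort
#'
#' Reference scaffolds, B sequence with planted blocks and diagnostic
#' variants, one read set per genotype, B contigs, and a triplicate Ct table
#' (three calibration controls per genotype class plus unknown samples with
#' withheld genotype).
#'
#' @param spec a [truth_spec()].
#' @param n_contigs number of simulated B contigs.
#' @param ct_a,ct_c_per_b,ct_a_ref,ct_replicates Ct-model parameters, see
#'   [simulate_ct()].
#' @param n_controls_per_class calibration controls per genotype class.
#' @param n_unknown unknown samples (true genotypes drawn uniformly, seeded;
#'   kept in `$truth_genotypes` for evaluation).
#' @return object of class `cohort`.
#' @export
simulate_cohort <- function(spec, n_contigs = 40L,
                            ct_a = 2, ct_c_per_b = 100, ct_a_ref = 2,
                            ct_replicates = 3L,
                            n_controls_per_class = 3L, n_unknown = 9L) {
  reference <- make_reference(spec$seed, spec$scaffold_lengths)
  b <- make_b_sequence(reference, spec)
  reads <- lapply(c("0B", "1B", "2B"), function(g)
    simulate_reads(reference, b, g, spec))
  names(reads) <- c("0B", "1B", "2B")
  contigs <- simulate_b_contigs(b, n_contigs, seed = spec$seed)
  classes <- c("0B", "1B", "2B")
  controls <- stats::setNames(rep(classes, each = n_controls_per_class),
                              sprintf("ctrl_%s_%d",
                                      rep(classes, each = n_controls_per_class),
                                      rep(seq_len(n_controls_per_class), 3)))
  unknown <- withr::with_seed(derive_seed(spec$seed, "unknown_genotypes"), {
    stats::setNames(sample(classes, n_unknown, replace = TRUE),
                    sprintf("unknown_%02d", seq_len(n_unknown)))
  })
  genotypes <- c(controls, unknown)
  ct <- simulate_ct(genotypes, a = ct_a, c_per_b = ct_c_per_b,
                    a_ref = ct_a_ref, c0 = spec$ct_baseline,
                    noise_sd = spec$ct_noise_sd, replicates = ct_replicates,
                    seed = spec$seed,
                    known = c(rep(TRUE, length(controls)),
                              rep(FALSE, length(unknown))))
  structure(list(spec = spec, reference = reference, b = b, reads = reads,
                 contigs = contigs, ct_table = ct,
                 truth_genotypes = genotypes), class = "cohort")
}

#' Coverage scan of a cohort
#'
#' Maps each genotype's reads with the built-in exact-seed mapper, windows
#' the depth, forms the 1B/0B and 2B/0B ratio track and detects and ranks
#' candidate B-enriched blocks.
#'
#' @param cohort a `cohort`.
#' @param cfg a [pipeline_config()].
#' @return list with `profiles`, `track`, `blocks` (ranked).
#' @export
scan_cohort <- function(cohort, cfg = pipeline_config(seed = cohort$spec$seed)) {
  lens <- cohort$spec$scaffold_lengths
  profiles <- lapply(names(cohort$reads), function(g) {
    m <- map_reads_exact(cohort$reads[[g]], cohort$reference,
                         k = cfg$mapper_k,
                         max_mismatches = cfg$mapper_max_mismatches)
    window_depth(m$placements, lens, cfg$window_size,
                 sample_id = g, genotype = g)
  })
  names(profiles) <- names(cohort$reads)
  track <- ratio_track(profiles[["0B"]], profiles[["1B"]], profiles[["2B"]],
                       alpha = cfg$alpha)
  blocks <- detect_blocks(track, theta = cfg$theta,
                          min_windows = cfg$min_windows,
                          max_gap = cfg$max_gap)
  if (nrow(blocks) > 0L) blocks <- rank_blocks(blocks)
  list(profiles = profiles, track = track, blocks = blocks)
}

#' Design a presence/absence multiplex assay for a cohort
#'
#' Works inside a candidate region (by default the top-ranked detected
#' block): builds an ortholog panel and its consensus over the region,
#' aligns each simulated B contig, calls B-diagnostic variants, and tries
#' variants in turn until a full three-primer assay passes assembly.
#'
#' @param cohort a `cohort`.
#' @param region one block row (data.frame with `scaffold`, `start`, `end`).
#' @param cfg a [pipeline_config()].
#' @return list with `assay`, `region`, `consensus`, `variant`,
#'   `b_template` (region sequence carrying the B alleles) and
#'   `a_template` (reference region sequence), or a `design_failure`.
#' @export
design_assay <- function(cohort, region, cfg = pipeline_config(seed = cohort$spec$seed)) {
  ref_seq <- Biostrings::subseq(cohort$reference[[region$scaffold]],
                                region$start + 1L, region$end)
  panel <- simulate_reference_panel(ref_seq, n_species = cfg$panel_species,
                                    divergence = cfg$panel_divergence,
                                    seed = cohort$spec$seed)
  cons <- build_consensus(panel)
  len_range <- c(cfg$primer_len_lo, cfg$primer_len_hi)
  tm_range <- c(cfg$tm_lo, cfg$tm_hi)
  failures <- character(0)
  for (ci in seq_along(cohort$contigs)) {
    contig <- as.character(cohort$contigs[[ci]])
    aln <- align_contig(contig, as.character(ref_seq))
    if (!aln$aligned || aln$strand != "+") next
    # primer extraction assumes a collinear, gap-free contig/region mapping
    if (grepl("[ID]", aln$ops)) next
    vars <- call_diagnostic_variants(aln, cons, min_flank = cfg$min_flank)
    if (nrow(vars) == 0L) next
    for (vi in seq_len(nrow(vars))) {
      v <- vars[vi, ]
      # the primer body must stay inside both the aligned contig segment and
      # the template, or it cannot bind the B template end-to-end
      avail <- min(v$contig_pos - aln$contig_start, v$position) + 1L
      if (avail < len_range[1]) next
      len_range_v <- c(len_range[1], min(len_range[2], avail))
      bf <- design_allele_specific_primer(v, contig, len_range_v, tm_range,
                                          id = sprintf("%s-B-F", names(cohort$contigs)[ci]))
      if (inherits(bf, "design_failure")) { failures <- c(failures, bf$reason); next }
      pair <- design_control_pair(cons, v$position, len_range, tm_range,
                                  product_range = c(cfg$control_product_lo,
                                                    cfg$control_product_hi),
                                  min_variant_offset = cfg$delta_gel + 5L,
                                  search_start = aln$ref_start,
                                  search_end = aln$ref_end,
                                  exclude = aln$mismatches$ref_pos)
      if (inherits(pair, "design_failure")) { failures <- c(failures, pair$reason); next }
      assay <- assemble_multiplex(bf, pair$control_forward, pair$shared_reverse,
                                  delta_gel = cfg$delta_gel,
                                  tm_span_max = cfg$tm_span_max,
                                  dimer_max_run = cfg$dimer_max_run)
      if (inherits(assay, "design_failure")) { failures <- c(failures, assay$reason); next }
      # B-positive template: the region carrying every planted B allele
      b_template <- .apply_variants(as.character(ref_seq),
                                    cohort$b$truth_variants, region)
      return(list(assay = assay, region = region, consensus = cons,
                  variant = v, b_template = b_template,
                  a_template = as.character(ref_seq)))
    }
  }
  .design_failure("no contig/variant yielded a feasible assay",
                  unique(failures))
}

# substitute B alleles of truth variants falling inside `region` into seq
.apply_variants <- function(seq, variants, region) {
  v <- variants[variants$scaffold == region$scaffold &
                variants$pos >= region$start & variants$pos < region$end, ,
                drop = FALSE]
  if (nrow(v) == 0L) return(seq)
  ch <- strsplit(seq, "")[[1]]
  ch[v$pos - region$start + 1L] <- v$alt
  paste(ch, collapse = "")
}

#' Run the full pipeline on a synthetic cohort
#'
#' simulate -> scan -> design -> in-silico PCR -> qPCR dose genotyping, with a
#' machine-readable report. Any stage failure aborts with a stage-named
#' error. The same config and seed always produce the same report.
#'
#' @param cfg a [pipeline_config()].
#' @param outdir optional output directory; when given, intermediate
#'   artifacts (FASTA/FASTQ/BED/TSV/CSV) and `report.json` are written there.
#' @return the report list, invisibly when `outdir` is given.
#' @export
run_pipeline <- function(cfg = pipeline_config(), outdir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .abort("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) if (isTRUE(cfg$verbose)) message(sprintf(...))

  log_msg("simulate: seed %d", cfg$seed)
  spec <- .spec_from_config(cfg)
  cohort <- stage("simulate", simulate_cohort(
    spec, n_contigs = cfg$n_contigs, ct_a = cfg$ct_a,
    ct_c_per_b = cfg$ct_c_per_b, ct_a_ref = cfg$ct_a_ref,
    ct_replicates = cfg$ct_replicates,
    n_controls_per_class = cfg$n_controls_per_class,
    n_unknown = cfg$n_unknown))

  log_msg("scan: window %d bp, theta %.2f", cfg$window_size, cfg$theta)
  scan <- stage("scan", scan_cohort(cohort, cfg))
  if (nrow(scan$blocks) == 0L) .abort("stage 'scan' failed: no blocks detected")

  log_msg("design: top block %s:%d-%d", scan$blocks$scaffold[1],
          scan$blocks$start[1], scan$blocks$end[1])
  design <- stage("design", design_assay(cohort, scan$blocks[1, ], cfg))
  if (inherits(design, "design_failure"))
    .abort("stage 'design' failed: %s", design$reason)

  log_msg("pcr: in-silico validation")
  pcr <- stage("pcr", {
    hits_b <- in_silico_pcr(design$b_template, design$assay,
                            max_product = cfg$max_product,
                            m_internal = cfg$m_internal,
                            template_id = "B_positive")
    hits_a <- in_silico_pcr(design$a_template, design$assay,
                            max_product = cfg$max_product,
                            m_internal = cfg$m_internal,
                            template_id = "B_negative")
    list(hits_b = hits_b, hits_a = hits_a,
         call_b = call_presence(hits_b, design$assay, cfg$presence_length_tol),
         call_a = call_presence(hits_a, design$assay, cfg$presence_length_tol))
  })

  log_msg("dose: GDR genotyping")
  dose <- stage("dose", {
    est <- dose_estimates(cohort$ct_table, sd_flag = cfg$sd_flag)
    cal <- calibrate(est)
    unknown <- est[is.na(est$genotype), , drop = FALSE]
    calls <- call_copies(unknown, cal, epsilon = cfg$epsilon)
    truth <- cohort$truth_genotypes[calls$sample_id]
    list(estimates = est, calibration = cal, calls = calls,
         concordance = mean(calls$genotype == truth))
  })

  report <- list(
    parameters = unclass(cfg),
    truth = list(block = cohort$b$truth_blocks,
                 n_variants = nrow(cohort$b$truth_variants)),
    scan = list(n_blocks = nrow(scan$blocks),
                top_block = scan$blocks[1, ]),
    assay = list(
      b_forward = design$assay$b_forward$sequence,
      control_forward = design$assay$control_forward$sequence,
      shared_reverse = design$assay$shared_reverse$sequence,
      expected_control_length = design$assay$expected_control_length,
      expected_b_length = design$assay$expected_b_length),
    pcr = list(n_products_b_positive = nrow(pcr$hits_b),
               n_products_b_negative = nrow(pcr$hits_a),
               call_b_positive = pcr$call_b$value,
               call_b_negative = pcr$call_a$value),
    dose = list(calibration = dose$calibration,
                calls = dose$calls,
                concordance = dose$concordance))

  if (!is.null(outdir)) {
    stage("write", {
      write_fasta(cohort$reference, file.path(outdir, "reference.fasta"))
      write_fasta(Biostrings::DNAStringSet(stats::setNames(
        as.character(cohort$b$b_sequence), "B_chromosome")),
        file.path(outdir, "b_sequence.fasta"))
      write_fasta(cohort$contigs, file.path(outdir, "b_contigs.fasta"))
      for (g in names(cohort$reads))
        write_fastq(cohort$reads[[g]], file.path(outdir, sprintf("reads_%s.fastq", g)))
      write_bed(cohort$b$truth_blocks, file.path(outdir, "truth_blocks.bed"))
      write.table(cohort$b$truth_variants, file.path(outdir, "truth_variants.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write_bed(scan$blocks, file.path(outdir, "detected_blocks.bed"))
      write_ct_csv(cohort$ct_table, file.path(outdir, "ct_table.csv"))
      write_primer_tsv(list(design$assay$b_forward, design$assay$control_forward,
                            design$assay$shared_reverse),
                       file.path(outdir, "assay_primers.tsv"))
      write_report_json(report, file.path(outdir, "report.json"))
    })
    return(invisible(report))
  }
  report
}

#' Jaccard overlap of two intervals
#'
#' Intersection over union of `[s1, e1)` and `[s2, e2)`; the standard measure
#' of how well a detected block recovers a planted one.
#'
#' @param s1,e1,s2,e2 interval bounds (0-based half-open).
#' @return numeric in `[0, 1]`.
#' @export
interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2))
  uni <- (e1 - s1) + (e2 - s2) - inter
  if (uni <= 0) return(0)
  inter / uni
}
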