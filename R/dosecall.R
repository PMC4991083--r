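#' Aggregate replicate Ct values
#'
#' Arithmetic mean and sample SD over the replicates of one (sample, assay);
#' replicates with SD above `sd_flag` cycles are flagged as unstable.
#'
#' @param replicates numeric vector of Ct values (>= 2, all > 0).
#' @param sd_flag SD flag threshold in cycles, default 0.5.
#' @return list with `mean`, `sd`, `flagged`.
#' @export
aggregate_ct <- function(replicates, sd_flag = 0.5) {
  if (length(replicates) < 2L) .abort("need at least 2 Ct replicates")
  if (any(!is.finite(replicates)) || any(replicates <= 0))
    .abort("Ct values must be positive and finite")
  s <- sd(replicates)
  list(mean = mean(replicates), sd = s, flagged = s > sd_flag)
}

#' Gene dose ratio of one sample
#'
#' `dCt = Ct_target - Ct_HPRT` and `GDR = 2^-dCt`; replicate SDs combine in
#' quadrature into a GDR uncertainty interval `2^-(dCt +/- sd)`.
#'
#' @param ct_target_mean,ct_ref_mean mean Ct of the target and reference
#'   (HPRT) assays.
#' @param sd_target,sd_ref replicate SDs (cycles).
#' @param sample_id label.
#' @return one-row data.frame of class `dose_estimate`: `sample_id`,
#'   `ct_target`, `ct_ref`, `sd_target`, `sd_ref`, `delta_ct`, `gdr`,
#'   `gdr_lo`, `gdr_hi`.
#' @export
gdr <- function(ct_target_mean, ct_ref_mean, sd_target = 0, sd_ref = 0,
                sample_id = NA_character_) {
  if (any(is.na(c(ct_target_mean, ct_ref_mean))))
    .abort("both assay means are required for sample %s", sample_id)
  d <- ct_target_mean - ct_ref_mean
  s <- sqrt(sd_target^2 + sd_ref^2)
  out <- data.frame(sample_id = sample_id, ct_target = ct_target_mean,
                    ct_ref = ct_ref_mean, sd_target = sd_target,
                    sd_ref = sd_ref, delta_ct = d, gdr = 2^(-d),
                    gdr_lo = 2^(-(d + s)), gdr_hi = 2^(-(d - s)),
                    stringsAsFactors = FALSE)
  class(out) <- c("dose_estimate", "data.frame")
  out
}

#' Per-sample dose estimates from a Ct table
#'
#' Aggregates triplicates per (sample, assay) and computes the gene dose
#' ratio of every sample. A sample missing either assay raises an error
#' naming it.
#'
#' @param ct_table data.frame with columns `sample_id`, `assay`
#'   (`"target"`/`"HPRT"`), `replicate`, `ct`, and optionally `genotype`.
#' @param sd_flag replicate-SD flag threshold (cycles).
#' @return data.frame, one row per sample: dose-estimate columns plus
#'   `genotype` (NA where unknown) and `flagged`.
#' @export
dose_estimates <- function(ct_table, sd_flag = 0.5) {
  need <- c("sample_id", "assay", "ct")
  if (!all(need %in% names(ct_table)))
    .abort("ct_table needs columns %s", paste(need, collapse = ", "))
  samples <- unique(ct_table$sample_id)
  rows <- lapply(samples, function(sid) {
    sub <- ct_table[ct_table$sample_id == sid, , drop = FALSE]
    tgt <- sub$ct[sub$assay == "target"]
    ref <- sub$ct[sub$assay == "HPRT"]
    if (length(tgt) == 0L || length(ref) == 0L)
      .abort("sample %s lacks a target or HPRT assay", sid)
    at <- aggregate_ct(tgt, sd_flag); ar <- aggregate_ct(ref, sd_flag)
    est <- gdr(at$mean, ar$mean, at$sd, ar$sd, sample_id = sid)
    est$genotype <- if ("genotype" %in% names(sub)) sub$genotype[1] else NA_character_
    est$flagged <- at$flagged || ar$flagged
    est
  })
  out <- do.call(rbind, rows)
  class(out) <- c("dose_estimate", "data.frame")
  out
}

#' Calibrate GDR cluster centers from known 0B/1B/2B controls
#'
#' Computes per-genotype GDR means and SDs and log2 cluster centers from
#' control samples of known genotype. The centers must be strictly ordered
#' `0B < 1B < 2B`; a violation invalidates dose discrimination and raises a
#' calibration-failure error.
#'
#' @param dose data.frame from [dose_estimates()] with a `genotype` column;
#'   rows with NA genotype are ignored.
#' @return object of class `calibration`: data.frame per genotype with
#'   `n`, `mean_gdr`, `sd_gdr`, `log2_center`.
#' @export
calibrate <- function(dose) {
  ctl <- dose[!is.na(dose$genotype), , drop = FALSE]
  classes <- c("0B", "1B", "2B")
  missing <- setdiff(classes, unique(ctl$genotype))
  if (length(missing) > 0L)
    .abort("calibration needs at least one control per class; missing: %s",
           paste(missing, collapse = ", "))
  tab <- do.call(rbind, lapply(classes, function(g) {
    x <- ctl$gdr[ctl$genotype == g]
    data.frame(genotype = g, n = length(x), mean_gdr = mean(x),
               sd_gdr = if (length(x) > 1L) sd(x) else 0,
               log2_center = log2(mean(x)), stringsAsFactors = FALSE)
  }))
  if (!(tab$mean_gdr[1] < tab$mean_gdr[2] && tab$mean_gdr[2] < tab$mean_gdr[3]))
    .abort("calibration-failure: control GDR means are not ordered 0B < 1B < 2B")
  structure(tab, class = c("calibration", "data.frame"))
}

#' Call B-chromosome copy number from dose estimates
#'
#' Nearest-center classification in log2 GDR space (dosage is multiplicative,
#' so log space gives symmetric thresholds): each sample gets the genotype of
#' the closest calibrated center, a fold change relative to the 1B control
#' mean, the log2 distance to its center, and an `ambiguous` flag when the
#' two nearest centers differ by less than `epsilon` log2 units in distance.
#'
#' @param dose data.frame from [dose_estimates()] (or a single [gdr()] row).
#' @param calibration a `calibration`.
#' @param epsilon ambiguity margin in log2 units, default 0.25.
#' @return data.frame, one row per sample: `sample_id`, `gdr`, `genotype`
#'   (the call), `fold_change_vs_1b`, `log2_distance`, `ambiguous`.
#' @export
call_copies <- function(dose, calibration, epsilon = 0.25) {
  centers <- calibration$log2_center
  names(centers) <- calibration$genotype
  mean_1b <- calibration$mean_gdr[calibration$genotype == "1B"]
  rows <- lapply(seq_len(nrow(dose)), function(i) {
    lg <- log2(dose$gdr[i])
    d <- abs(lg - centers)
    o <- order(d)
    data.frame(sample_id = dose$sample_id[i], gdr = dose$gdr[i],
               genotype = names(centers)[o[1]],
               fold_change_vs_1b = dose$gdr[i] / mean_1b,
               log2_distance = d[o[1]],
               ambiguous = (d[o[2]] - d[o[1]]) < epsilon,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cohort-level 2B/1B fold change of the gene dose ratio
#'
#' Ratio of the mean GDR of the 2B samples to that of the 1B samples, with a
#' seeded bootstrap percentile interval. Under the dose model the expectation
#' is `(a + 2c) / (a + c)` for `a` A-complement copies and `c` copies added
#' per B, approaching 2 as `c/a` grows — the two-fold signal expected of a
#' B-amplified block.
#'
#' @param gdr_2b,gdr_1b numeric GDR vectors (>= 1 value each).
#' @param n_boot bootstrap resamples, default 1000.
#' @param seed integer seed for the bootstrap.
#' @param conf interval coverage, default 0.95.
#' @return list with `ratio`, `ci` (length-2), `n_2b`, `n_1b`.
#' @export
cohort_fold_change <- function(gdr_2b, gdr_1b, n_boot = 1000L, seed = 1L,
                               conf = 0.95) {
  if (length(gdr_2b) < 1L || length(gdr_1b) < 1L)
    .abort("both classes need at least one sample")
  ratio <- mean(gdr_2b) / mean(gdr_1b)
  ci <- withr::with_seed(derive_seed(seed, "bootstrap"), {
    boots <- vapply(seq_len(n_boot), function(i) {
      mean(sample(gdr_2b, replace = TRUE)) / mean(sample(gdr_1b, replace = TRUE))
    }, 1)
    quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  })
  list(ratio = ratio, ci = ci, n_2b = length(gdr_2b), n_1b = length(gdr_1b))
}
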