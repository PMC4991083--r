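#' Read / write FASTA
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()].
#'
#' @param path file path.
#' @return a [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) .abort("FASTA file not found: %s", path)
  Biostrings::readDNAStringSet(path)
}

#' @rdname read_fasta
#' @param x a [Biostrings::DNAStringSet] (or coercible).
#' @export
write_fasta <- function(x, path) {
  if (!inherits(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read / write FASTQ (Phred+33)
#'
#' @param path file path.
#' @return a [Biostrings::DNAStringSet] (qualities are constant in simulated
#'   sets and are not retained).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) .abort("FASTQ file not found: %s", path)
  Biostrings::readDNAStringSet(path, format = "fastq")
}

#' @rdname read_fastq
#' @param x a `read_set` from [simulate_reads()] or a
#'   [Biostrings::DNAStringSet].
#' @export
write_fastq <- function(x, path) {
  if (inherits(x, "read_set")) {
    quals <- Biostrings::BStringSet(rep(x$qualities, length(x$reads)))
    x <- x$reads
  } else {
    quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(x)))
  }
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read alignments from SAM/BAM
#'
#' SAM files are converted to BAM internally (Rsamtools), then primary,
#' mapped, non-duplicate records are read. SAM's 1-based leftmost position is
#' converted to the package-wide 0-based half-open convention
#' (`pos = POS - 1`).
#'
#' @param path SAM or BAM file.
#' @param min_mapq minimum MAPQ kept (default 0; records with missing MAPQ
#'   are kept).
#' @return data.frame with `qname`, `rname`, `pos` (0-based), `mapq`;
#'   attribute `scaffold_lengths` carries the header's sequence lengths.
#' @export
read_alignments <- function(path, min_mapq = 0L) {
  if (!file.exists(path)) .abort("alignment file not found: %s", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isDuplicate = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag,
                                   what = c("qname", "rname", "pos", "mapq"))
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  keep <- is.na(res$mapq) | res$mapq >= min_mapq
  out <- data.frame(qname = res$qname[keep],
                    rname = as.character(res$rname[keep]),
                    pos = res$pos[keep] - 1L,
                    mapq = res$mapq[keep], stringsAsFactors = FALSE)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  attr(out, "scaffold_lengths") <- hdr
  out
}

#' Read / write BED intervals
#'
#' BED is 0-based half-open on disk, matching the package convention, so
#' coordinates round-trip unchanged.
#'
#' @param path file path.
#' @return data.frame with `scaffold`, `start`, `end` and, when present,
#'   `name` and `score`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) .abort("BED file not found: %s", path)
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(scaffold = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  if (!is.null(gr$name)) out$name <- gr$name
  if (!is.null(gr$score)) out$score <- gr$score
  out
}

#' @rdname read_bed
#' @param blocks data.frame with `scaffold`, `start`, `end` (0-based
#'   half-open) and optional `name`/`score` columns (block tables from
#'   [detect_blocks()] export `mean_r2` as the score).
#' @export
write_bed <- function(blocks, path) {
  name <- if (!is.null(blocks$name)) blocks$name else
    sprintf("block_%d", seq_len(nrow(blocks)))
  score <- if (!is.null(blocks$score)) blocks$score else
    if (!is.null(blocks$mean_r2)) blocks$mean_r2 else 0
  lines <- sprintf("%s\t%d\t%d\t%s\t%g", blocks$scaffold,
                   as.integer(blocks$start), as.integer(blocks$end),
                   name, score)
  writeLines(lines, path)
  invisible(path)
}

#' Read / write primer tables (TSV)
#'
#' Expected columns: `id`, `sequence`, and optionally `role`, `template`,
#' `coord`. When `role` is absent it is inferred from the id by the B/C/F/R
#' naming scheme: ids ending in `-R` are shared reverse primers (`R`), ids
#' whose suffix carries a `C` before the orientation are controls (`C`), and
#' the rest are B-specific (`B`).
#'
#' @param path TSV file.
#' @return data.frame with at least `id`, `sequence`, `role`.
#' @export
read_primer_tsv <- function(path) {
  if (!file.exists(path)) .abort("primer table not found: %s", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "sequence") %in% names(tab)))
    .abort("%s: primer table needs 'id' and 'sequence' columns", path)
  tab$sequence <- toupper(gsub("\\s", "", tab$sequence))
  bad <- grepl("[^ACGT]", tab$sequence)
  if (any(bad))
    .abort("%s: non-ACGT primer sequence at line %d (%s)", path,
           which(bad)[1] + 1L, tab$id[which(bad)[1]])
  if (is.null(tab$role)) {
    tab$role <- ifelse(grepl("-R$", tab$id), "R",
                       ifelse(grepl("C[^-]*-F$|C\\s*\\+", tab$id), "C", "B"))
  }
  tab
}

#' @rdname read_primer_tsv
#' @param primers data.frame (or list of `primer` objects).
#' @export
write_primer_tsv <- function(primers, path) {
  if (is.list(primers) && !is.data.frame(primers) &&
      all(vapply(primers, inherits, TRUE, "primer"))) {
    primers <- do.call(rbind, lapply(primers, function(p)
      data.frame(id = p$id, sequence = p$sequence, role = NA_character_,
                 template = NA_character_, coord = p$template_start,
                 stringsAsFactors = FALSE)))
  }
  write.table(primers, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write qPCR Ct tables (CSV)
#'
#' Schema: `sample_id`, optional `genotype` (0B/1B/2B or NA), `assay`
#' (`"target"` or `"HPRT"`), `replicate`, `ct`.
#'
#' @param path CSV file.
#' @return data.frame in the schema above.
#' @export
read_ct_csv <- function(path) {
  if (!file.exists(path)) .abort("Ct table not found: %s", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "assay", "replicate", "ct")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L)
    .abort("%s: Ct table missing columns: %s", path, paste(miss, collapse = ", "))
  if (!all(tab$assay %in% c("target", "HPRT")))
    .abort("%s: assay must be 'target' or 'HPRT'", path)
  if (any(!is.finite(tab$ct)) || any(tab$ct <= 0))
    .abort("%s: Ct values must be positive", path)
  tab
}

#' @rdname read_ct_csv
#' @param ct_table data.frame in the Ct schema.
#' @export
write_ct_csv <- function(ct_table, path) {
  write.csv(ct_table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a machine-readable JSON report
#'
#' @param x report list.
#' @param path output path.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Paths of the shipped fixture tables
#'
#' The package ships the qualitative-marker primer panel, the qPCR primer
#' panel, and the six selected high-coverage regions as plain-text fixtures.
#'
#' @param which one of `"qualitative_primers"`, `"qpcr_primers"`,
#'   `"qpcr_regions"`.
#' @return file path inside the installed package.
#' @export
fixture_path <- function(which = c("qualitative_primers", "qpcr_primers",
                                   "qpcr_regions")) {
  which <- match.arg(which)
  f <- switch(which,
              qualitative_primers = "qualitative_pcr_primers.tsv",
              qpcr_primers = "qpcr_primers.tsv",
              qpcr_regions = "qpcr_regions.bed")
  system.file("extdata", f, package = "bchromr", mustWork = TRUE)
}
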