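test_that("contig alignment recovers exact and mutated placements", {
  withr::with_seed(7, {
    ref <- random_seq(1200)
    contig <- substring(ref, 301, 600)
    a <- align_contig(contig, ref)
    expect_true(a$aligned)
    expect_equal(a$strand, "+")
    expect_equal(c(a$ref_start, a$ref_end), c(300, 600))
    expect_equal(c(a$contig_start, a$contig_end), c(0, 300))
    expect_equal(a$n_mismatches, 0)
    expect_equal(a$score, 300)
    # one substitution is reported at the planted offset
    mut <- mutate_at(contig, 150, setdiff(c("A", "C", "G", "T"),
                                          substring(contig, 151, 151))[1])
    a2 <- align_contig(mut, ref)
    expect_equal(a2$n_mismatches, 1)
    expect_equal(a2$mismatches$ref_pos, 450)
    expect_equal(a2$mismatches$contig_pos, 150)
    # reverse-complement orientation is found and mapped back
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(mut)))
    a3 <- align_contig(rc, ref)
    expect_true(a3$aligned)
    expect_equal(a3$strand, "-")
    expect_equal(c(a3$ref_start, a3$ref_end), c(300, 600))
    expect_equal(a3$n_mismatches, 1)
    expect_equal(a3$mismatches$ref_pos, 450)
    # unrelated sequence with no seed: no alignment, no error
    a4 <- align_contig(strrep("ACGT", 30), strrep("GGATC", 60))
    expect_false(a4$aligned)
  })
})

test_that("alignment score equals full Smith-Waterman on seeded homologies", {
  withr::with_seed(13, {
    for (i in 1:50) {
      ref <- random_seq(500)
      len <- sample(80:300, 1)
      at <- sample(0:(500 - len), 1)
      contig <- substring(ref, at + 1, at + len)
      nmut <- sample(0:8, 1)
      if (nmut > 0) {
        pos <- sample(len, nmut)
        ch <- strsplit(contig, "")[[1]]
        ch[pos] <- vapply(ch[pos], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
        contig <- paste(ch, collapse = "")
      }
      got <- align_contig(contig, ref)
      expect_true(got$aligned)
      expect_equal(got$score, sw_oracle_score(contig, ref))
    }
  })
})

test_that("consensus takes column majorities and marks conservation", {
  s <- c("ACGTACGT", "ACGTACGT", "ACGTACGT")
  cs <- build_consensus(s)
  expect_identical(cs$consensus, "ACGTACGT")
  expect_true(all(cs$conserved))
  # majority column {A,A,G}: consensus A, not conserved
  cs2 <- build_consensus(c("AACG", "AACG", "GACG"))
  expect_identical(substring(cs2$consensus, 1, 1), "A")
  expect_false(cs2$conserved[1])
  expect_true(all(cs2$conserved[2:4]))
  # two-sequence tie {A,G} -> IUPAC R, non-conserved
  cs3 <- build_consensus(c("ATT", "GTT"))
  expect_identical(substring(cs3$consensus, 1, 1), "R")
  expect_false(cs3$conserved[1])
  expect_error(build_consensus(c("ACGT")), "at least 2")
})

test_that("diagnostic variant calling needs conservation and flanks", {
  withr::with_seed(17, {
    region <- random_seq(400)
    panel <- c(region, region, region)   # fully conserved panel
    cons <- build_consensus(panel)
    contig <- region
    aln <- align_contig(contig, region)
    expect_equal(nrow(call_diagnostic_variants(aln, cons)), 0)
    # planted substitution with 20 conserved flanking columns on each side
    b_base <- setdiff(c("A", "C", "G", "T"), substring(region, 201, 201))[1]
    contig2 <- mutate_at(region, 200, b_base)
    v <- call_diagnostic_variants(align_contig(contig2, region), cons,
                                  min_flank = 20)
    expect_equal(nrow(v), 1)
    expect_equal(v$position, 200)
    expect_identical(v$b_base, b_base)
    expect_identical(v$consensus_base, substring(region, 201, 201))
    # the same substitution at a non-conserved column is excluded
    panel_nc <- panel
    panel_nc[2] <- mutate_at(panel_nc[2], 200,
                             setdiff(c("A", "C", "G", "T"),
                                     c(substring(region, 201, 201), b_base))[1])
    cons_nc <- build_consensus(panel_nc)
    expect_equal(nrow(call_diagnostic_variants(align_contig(contig2, region),
                                               cons_nc, min_flank = 20)), 0)
    # insufficient flank conservation is excluded
    panel_fl <- panel
    panel_fl[2] <- mutate_at(panel_fl[2], 210, "A")
    panel_fl[2] <- mutate_at(panel_fl[2], 210,
                             setdiff(c("A", "C", "G", "T"),
                                     substring(region, 211, 211))[1])
    cons_fl <- build_consensus(panel_fl)
    expect_equal(nrow(call_diagnostic_variants(align_contig(contig2, region),
                                               cons_fl, min_flank = 20)), 0)
  })
})

test_that("melting temperatures match the Wallace rule and a thermodynamic oracle", {
  expect_equal(melting_temp("ACGT", mode = "wallace"), 12)
  expect_equal(melting_temp("AAAA", mode = "wallace"), 8)
  # frozen values from an independent nearest-neighbor implementation
  # (unified parameters, 50 mM Na+, 0.25 uM total strands)
  oracle <- c("GCTTCACACTTGCAGAGGTAAGTCATTTTT" = 60.0266,
              "CCTGATTGAGTGCTTCTCACAC" = 55.4714,
              "AGAATGGTCCAAGGAAGG" = 49.9663,
              "AGCATGGTGGCAGAGGTCTTTA" = 57.7408,
              "CGTTTTGTACGTCTGCTGGA" = 55.0060,
              "TGTTTGAGCATCCCCCAGAC" = 56.3126)
  got <- melting_temp(names(oracle))
  expect_true(all(abs(got - oracle) < 2))
  expect_error(melting_temp("ACGTNACG"), "A/C/G/T")
  expect_error(melting_temp("ACGTACG"), "length >= 8")
})

test_that("allele-specific primers end on the B allele at a feasible Tm", {
  withr::with_seed(23, {
    contig <- random_seq(300)
    b_base <- substring(contig, 201, 201)
    v <- data.frame(position = 500, contig_pos = 200, b_base = b_base,
                    consensus_base = "N")
    p <- design_allele_specific_primer(v, contig)
    expect_s3_class(p, "primer")
    expect_identical(substring(p$sequence, p$length, p$length), b_base)
    expect_true(p$tm >= 55 && p$tm <= 65)
    expect_equal(p$end3, 500)
    expect_equal(p$template_end - p$template_start, p$length)
    # optimality: no feasible length sits closer to the window midpoint
    lens <- 18:40
    cands <- substring(contig, 201 - lens + 1, 201)
    tms <- melting_temp(cands)
    feas <- tms >= 55 & tms <= 65
    expect_equal(abs(p$tm - 60), min(abs(tms[feas] - 60)))
    # an all-G upstream window melts far above the window: design failure
    gcontig <- paste0(strrep("G", 60), "T")
    vg <- data.frame(position = 60, contig_pos = 60, b_base = "T")
    expect_s3_class(design_allele_specific_primer(vg, gcontig),
                    "design_failure")
  })
})

test_that("control pairs sit in conserved sequence and bracket a sized product", {
  withr::with_seed(29, {
    region <- random_seq(600)
    cons <- build_consensus(c(region, region, region))  # fully conserved
    pair <- design_control_pair(cons, variant_pos = 50)
    expect_false(inherits(pair, "design_failure"))
    cf <- pair$control_forward; sr <- pair$shared_reverse
    prod <- sr$template_end - cf$template_start
    expect_true(prod >= 120 && prod <= 220)
    expect_true(all(c(cf$tm, sr$tm) >= 55 & c(cf$tm, sr$tm) <= 65))
    expect_identical(substring(region, cf$template_start + 1, cf$template_end),
                     cf$sequence)
    expect_identical(sr$sequence,
                     as.character(Biostrings::reverseComplement(
                       Biostrings::DNAString(substring(region,
                                                       sr$template_start + 1,
                                                       sr$template_end)))))
    # primers never overlap non-conserved columns
    cons2 <- cons
    for (i in 1:30) {
      region_i <- random_seq(600)
      panel_i <- simulate_reference_panel(region_i, divergence = 0.03, seed = i)
      cons_i <- build_consensus(panel_i)
      pr <- design_control_pair(cons_i, variant_pos = 30)
      if (inherits(pr, "design_failure")) next
      for (p in pr)
        expect_true(all(cons_i$conserved[(p$template_start + 1):p$template_end]))
    }
    # conserved runs shorter than a primer: failure
    alt <- vapply(seq_len(600), function(i)
      if (i %% 10 == 0) "A" else substring(region, i, i), "")
    broken <- build_consensus(c(region, paste(alt, collapse = "")))
    expect_s3_class(design_control_pair(broken, variant_pos = 50),
                    "design_failure")
  })
})

test_that("multiplex assembly enforces gel gap, Tm span and dimer rules", {
  mk <- function(seq, strand, s, e, tm = 60, id = seq)
    primer(id, seq, strand, s, e, tm = tm)
  withr::with_seed(31, {
    sA <- random_seq(30); sB <- random_seq(20); sC <- random_seq(18)
    # geometry reproducing a 163 bp control and 260 bp B product
    b_f <- mk(sA, "+", 0, 30, id = "B-F")
    c_f <- mk(sB, "+", 97, 117, id = "C-F")
    r_p <- mk(sC, "-", 242, 260, id = "R")
    asy <- assemble_multiplex(b_f, c_f, r_p, delta_gel = 40)
    expect_s3_class(asy, "multiplex_assay")
    expect_equal(asy$expected_control_length, 163)
    expect_equal(asy$expected_b_length, 260)
    expect_equal(asy$constraint_report$size_gap, 97)
    # equal product sizes are gel-unresolvable
    fail <- assemble_multiplex(mk(sA, "+", 97, 127, id = "B-F"), c_f, r_p)
    expect_s3_class(fail, "design_failure")
    expect_match(fail$reason, "unresolvable")
    # Tm span above the limit is rejected
    hot <- mk(sB, "+", 97, 117, tm = 70, id = "C-F")
    expect_s3_class(assemble_multiplex(b_f, hot, r_p), "design_failure")
    # 6 nt mutual 3' reverse-complement: dimer rejection
    tail6 <- substring(sA, 25, 30)
    dimer_seq <- paste0(random_seq(14),
                        as.character(Biostrings::reverseComplement(
                          Biostrings::DNAString(tail6))))
    dimer <- mk(dimer_seq, "+", 97, 117, id = "C-F")
    res <- assemble_multiplex(b_f, dimer, r_p)
    expect_s3_class(res, "design_failure")
    expect_match(res$reason, "dimer")
  })
})

test_that("in-silico PCR matches a brute-force site scan on random templates", {
  withr::with_seed(37, {
    for (i in 1:12) {
      tpl <- random_seq(2000)
      # plant near-exact binding sites for a synthetic primer pair
      fwd <- substring(tpl, 301, 322)
      rev_site <- substring(tpl, 801, 820)
      rev <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(rev_site)))
      ps <- list(primer("F", fwd, "+"), primer("R", rev, "-"))
      got <- in_silico_pcr(tpl, ps, max_product = 1000, m_internal = 3)
      want <- brute_pcr(tpl, ps, max_product = 1000, m_internal = 3)
      o1 <- got[order(got$start, got$end, got$fwd_id, got$rev_id),
                c("start", "end", "length", "fwd_id", "rev_id")]
      o2 <- want[order(want$start, want$end, want$fwd_id, want$rev_id), ]
      rownames(o1) <- rownames(o2) <- NULL
      expect_equal(o1, o2)
      expect_true(any(got$length == 520))
    }
  })
})

test_that("a 3'-terminal mismatch abolishes priming", {
  withr::with_seed(41, {
    tpl <- random_seq(600)
    fwd <- substring(tpl, 101, 124)
    rev <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substring(tpl, 381, 400))))
    ps <- list(primer("F", fwd, "+"), primer("R", rev, "-"))
    expect_equal(nrow(in_silico_pcr(tpl, ps)), 1)
    # break the forward primer's 3' base on the template
    last <- substring(tpl, 124, 124)
    tpl2 <- mutate_at(tpl, 123, setdiff(c("A", "C", "G", "T"), last)[1])
    hits2 <- in_silico_pcr(tpl2, ps)
    expect_false("F" %in% hits2$fwd_id)
  })
})

test_that("presence calls follow the two-band / one-band gel logic", {
  asy <- list(b_forward = list(id = "B-F"), control_forward = list(id = "C-F"),
              shared_reverse = list(id = "R"),
              expected_control_length = 163, expected_b_length = 260)
  class(asy) <- "multiplex_assay"
  hit <- function(len, fwd) data.frame(template_id = "t", start = 0, end = len,
                                       length = len, fwd_id = fwd, rev_id = "R",
                                       mm_fwd = 0, mm_rev = 0)
  both <- rbind(hit(163, "C-F"), hit(260, "B-F"))
  expect_identical(call_presence(both, asy)$value, "B_positive")
  expect_identical(call_presence(hit(163, "C-F"), asy)$value, "B_negative")
  expect_identical(call_presence(hit(260, "B-F"), asy)$value, "invalid")
})

test_that("design/PCR round trip gives two bands on B+ and one on B- templates", {
  n_ok <- 0
  for (seed in 1:20) {
    co <- make_light_cohort(seed, n_contigs = 30)
    region <- co$b$truth_blocks[1, ]
    d <- design_assay(co, region)
    if (inherits(d, "design_failure")) next
    n_ok <- n_ok + 1
    # every feasible design: ARMS primer 3' base is the B allele
    expect_identical(substring(d$assay$b_forward$sequence,
                               d$assay$b_forward$length,
                               d$assay$b_forward$length),
                     d$variant$b_base)
    hits_b <- in_silico_pcr(d$b_template, d$assay)
    hits_a <- in_silico_pcr(d$a_template, d$assay)
    expect_equal(nrow(hits_b), 2)
    expect_equal(nrow(hits_a), 1)
    expect_identical(call_presence(hits_b, d$assay)$value, "B_positive")
    expect_identical(call_presence(hits_a, d$assay)$value, "B_negative")
    # amplicon length identity
    expect_equal(hits_b$length, hits_b$end - hits_b$start)
  }
  expect_gte(n_ok, 15)
})
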