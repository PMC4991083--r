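test_that("window counting follows the leftmost-base rule and conserves reads", {
  lens <- c(sc = 500L)
  aln <- data.frame(rname = "sc", pos = 10L)
  p <- window_depth(aln, lens, window_size = 100)
  expect_identical(p$counts$sc, c(1L, 0L, 0L, 0L, 0L))
  # read starting at 99 with a 50 bp span counts in window 0 only
  p2 <- window_depth(data.frame(rname = "sc", pos = 99L), lens, 100)
  expect_identical(p2$counts$sc, c(1L, 0L, 0L, 0L, 0L))
  # empty input: all-zero profile, zero library
  p0 <- window_depth(data.frame(rname = character(0), pos = integer(0)),
                     lens, 100)
  expect_true(all(p0$counts$sc == 0L))
  expect_equal(p0$library_size, 0L)
  # conservation over a random placement set
  pos <- sample.int(500, 200, replace = TRUE) - 1L
  pr <- window_depth(data.frame(rname = "sc", pos = pos), lens, 100)
  expect_equal(sum(unlist(pr$counts)), pr$library_size)
  expect_error(window_depth(data.frame(rname = "other", pos = 1L), lens, 100),
               "other")
  expect_error(window_depth(aln, lens, window_size = 10), ">= 50")
})

test_that("normalization is reads-per-million and rejects empty libraries", {
  p <- fake_profile(list(sc = c(50L, 0L)), library_size = 1e6)
  expect_equal(normalize_depth(p)$sc, c(50, 0))
  # proportional counts normalize to equal tracks
  a <- fake_profile(list(sc = c(10L, 30L)), library_size = 40)
  b <- fake_profile(list(sc = c(20L, 60L)), library_size = 80)
  expect_equal(normalize_depth(a), normalize_depth(b))
  expect_error(normalize_depth(fake_profile(list(sc = c(0L)), 0)), "> 0")
})

test_that("ratio track uses pseudocounted normalized depths", {
  # counts chosen so normalized depths are nd0 = 4, nd1 = 9 (alpha = 1 -> r1 = 2)
  p0 <- fake_profile(list(sc = c(4L, 0L)), library_size = 1e6)
  p1 <- fake_profile(list(sc = c(9L, 0L)), library_size = 1e6)
  p2 <- fake_profile(list(sc = c(0L, 0L)), library_size = 1e6)
  tr <- ratio_track(p0, p1, p2, alpha = 1)
  expect_equal(tr$r1[1], 2)
  # empty windows fall back to 1 via the pseudocount
  expect_equal(tr$r1[2], 1)
  expect_equal(tr$r2[2], 1)
  # a sample against itself is identically 1
  trs <- ratio_track(p1, p1, p1, alpha = 0.5)
  expect_true(all(trs$r1 == 1) && all(trs$r2 == 1))
  bad <- fake_profile(list(sc = c(1L, 1L)), 10, window_size = 200L)
  expect_error(ratio_track(p0, p1, bad), "window")
})

test_that("block detection merges threshold runs and tolerates gaps", {
  mk_track <- function(r1, r2, w = 100L) {
    n <- length(r1)
    structure(data.frame(scaffold = "sc", window = seq_len(n) - 1L,
                         start = (seq_len(n) - 1L) * w, end = seq_len(n) * w,
                         nd0 = 1, nd1 = 1, nd2 = 1, r1 = r1, r2 = r2),
              window_size = w, alpha = 0.5,
              scaffold_lengths = c(sc = n * w),
              class = c("ratio_track", "data.frame"))
  }
  tr <- mk_track(c(1, 1, 3, 3.1, 3, 1), c(1, 1, 3, 3.1, 3, 1))
  bl <- detect_blocks(tr, theta = 1.5, min_windows = 2, max_gap = 1)
  expect_equal(nrow(bl), 1)
  expect_equal(bl$start, 200)
  expect_equal(bl$end, 500)
  expect_equal(bl$n_windows, 3)
  # all-background track yields nothing
  expect_equal(nrow(detect_blocks(mk_track(rep(1, 6), rep(1, 6)))), 0)
  # gap bridging: pass-fail-pass-pass within max_gap = 1 is one block
  tr2 <- mk_track(c(3, 1, 3, 3, 1, 1), c(3, 1, 3, 3, 1, 1))
  bl2 <- detect_blocks(tr2, theta = 1.5, min_windows = 3, max_gap = 1)
  expect_equal(nrow(bl2), 1)
  expect_equal(c(bl2$start, bl2$end), c(0, 400))
  # both ratios must clear the threshold ("exclusive to B genomes")
  tr3 <- mk_track(c(3, 3, 3), c(1, 1, 1))
  expect_equal(nrow(detect_blocks(tr3, min_windows = 2)), 0)
  # brute-force cross-check over random tracks: passing windows grouped by
  # gap <= max_gap, kept when >= min_windows
  withr::with_seed(99, {
    for (rep in 1:20) {
      n <- 30
      r <- ifelse(runif(n) < 0.3, 3, 1)
      tr <- mk_track(r, r)
      got <- detect_blocks(tr, theta = 1.5, min_windows = 2, max_gap = 1)
      pass <- which(r >= 1.5)
      expected <- 0L
      if (length(pass) > 0) {
        grp <- cumsum(c(1, diff(pass) > 2))
        expected <- sum(table(grp) >= 2)
      }
      expect_equal(nrow(got), expected)
    }
  })
})

test_that("detection ignores added all-background scaffolds", {
  p0 <- fake_profile(list(sc = c(rep(10, 7), 10, 10, 10)), 100)
  p1 <- fake_profile(list(sc = c(rep(10, 7), 60, 60, 60)), 250)
  p2 <- fake_profile(list(sc = c(rep(10, 7), 110, 110, 110)), 400)
  bl1 <- detect_blocks(ratio_track(p0, p1, p2), theta = 1.5, min_windows = 2)
  expect_equal(nrow(bl1), 1)
  # a true background scaffold has equal normalized depth in every sample,
  # i.e. window counts proportional to each library size
  add_bg <- function(p) {
    p$counts$bg <- rep(p$library_size / 4, 4)
    p$scaffold_lengths <- c(p$scaffold_lengths, bg = 400L)
    p$library_size <- 2 * p$library_size
    p
  }
  bl2 <- detect_blocks(ratio_track(add_bg(p0), add_bg(p1), add_bg(p2)),
                       theta = 1.5, min_windows = 2)
  expect_equal(bl2[bl2$scaffold == "sc", c("start", "end")],
               bl1[, c("start", "end")])
})

test_that("block ranking prefers dose-consistent, stable blocks", {
  bl <- data.frame(scaffold = c("a", "b", "c"), start = c(0, 0, 0),
                   end = c(100, 100, 100), n_windows = 2,
                   mean_r1 = c(2, 2, 2), mean_r2 = c(3, 3.5, 3),
                   cv_r2 = c(0.5, 0.1, 0.1),
                   dose_consistency = c(0.4, 0.05, 0.05))
  r <- rank_blocks(bl)
  expect_identical(r$scaffold, c("b", "c", "a"))
  single <- bl[1, ]
  expect_identical(rank_blocks(single), single)
  expect_error(rank_blocks(bl[0, ]), "at least one")
})

test_that("block size is end minus start on 0-based half-open coordinates", {
  expect_equal(block_size(data.frame(start = 9112721, end = 9126380)), 13659L)
  expect_equal(block_size(data.frame(start = 5682225, end = 5684956)), 2731L)
  expect_equal(block_size(data.frame(start = 7, end = 8)), 1L)
  expect_error(block_size(data.frame(start = 5, end = 5)), "end > start")
  # the shipped region fixture is internally consistent
  regions <- read_bed(fixture_path("qpcr_regions"))
  expect_identical(block_size(regions), c(13659L, 2731L, 2731L, 2731L, 6829L, 682L))
})

test_that("exact-seed mapper agrees with an exhaustive Hamming scan", {
  withr::with_seed(21, {
    ref <- make_reference(21, c(sc = 10000))
    ref_str <- as.character(ref[["sc"]])
    # error-free reads are placed exactly at their origin
    starts <- sample(0:(10000 - 80), 20)
    reads <- Biostrings::DNAStringSet(substring(ref_str, starts + 1, starts + 80))
    names(reads) <- sprintf("r%d", seq_along(starts))
    m <- map_reads_exact(reads, ref, k = 20)
    expect_equal(nrow(m$placements), 20)
    expect_equal(m$placements$pos[order(m$placements$qname)],
                 starts[order(names(reads))])
    # reads with up to 3 substitutions after the seed: oracle comparison
    reads2 <- character(50); origins <- sample(0:(10000 - 80), 50)
    for (i in 1:50) {
      s <- substring(ref_str, origins[i] + 1, origins[i] + 80)
      nmut <- sample(0:3, 1)
      if (nmut > 0) {
        at <- sample(21:80, nmut)   # keep the 20 bp seed intact
        ch <- strsplit(s, "")[[1]]
        ch[at] <- vapply(ch[at], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
        s <- paste(ch, collapse = "")
      }
      reads2[i] <- s
    }
    rs <- Biostrings::DNAStringSet(reads2)
    names(rs) <- sprintf("q%02d", 1:50)
    got <- map_reads_exact(rs, ref, k = 20, max_mismatches = 2)
    for (i in 1:50) {
      oracle <- brute_map(reads2[i], ref, max_mm = 2)
      row <- got$placements[got$placements$qname == sprintf("q%02d", i), ]
      if (is.null(oracle) || length(oracle$hits) > 1) {
        expect_equal(nrow(row), 0)
      } else if (nrow(row) == 1) {
        expect_equal(row$pos, as.integer(oracle$hits[[1]]["pos"]))
        expect_equal(row$mismatches, oracle$mm)
      } else {
        # seed-based mapper may miss placements whose mismatches hit the seed
        expect_gt(oracle$mm, 0)
      }
    }
  })
})

test_that("normalized block ratios follow the closed-form dose expectation", {
  # with RPM normalization the block ratio is ((a + nB c f)/a) * (P0 / PnB):
  # Pg is the genotype's template pool size and f the mappable fraction of
  # B-copy reads (reads straddling a copy junction have no reference match)
  spec <- truth_spec(seed = 31, scaffold_lengths = c(sc = 10000),
                     b_blocks = data.frame(scaffold = "sc", start = 3000,
                                           end = 5000, copies_on_b = 10),
                     snv_rate_in_blocks = 0, depth_per_haploid_copy = 30,
                     read_error_rate = 0)
  ref <- make_reference(spec$seed, spec$scaffold_lengths)
  b <- make_b_sequence(ref, spec)
  prof <- lapply(c("0B", "1B", "2B"), function(g) {
    m <- map_reads_exact(simulate_reads(ref, b, g, spec), ref)
    window_depth(m$placements, spec$scaffold_lengths, 1000, sample_id = g)
  })
  tr <- ratio_track(prof[[1]], prof[[2]], prof[[3]])
  blk <- tr$start >= 3000 & tr$end <= 5000
  a <- 2; cc <- 10
  f <- 1 - (spec$read_length - 1) / 2000
  p0 <- a * 10000; p1 <- p0 + cc * 2000; p2 <- p0 + 2 * cc * 2000
  expect_lt(abs(mean(tr$r1[blk]) - ((a + cc * f) / a) * (p0 / p1)), 0.3)
  expect_lt(abs(mean(tr$r2[blk]) - ((a + 2 * cc * f) / a) * (p0 / p2)), 0.4)
  # background windows sit near the pool-size ratio, well under threshold
  bg <- tr$start >= 6000
  expect_lt(mean(tr$r1[bg]), 1.2)
})
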