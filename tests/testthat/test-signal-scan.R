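# Triplet profiles, window statistics, breakpoint demarcation, event
# consolidation and scan-level invariants.

test_that("triplet profile keeps only 2-vs-1 ungapped columns", {
  a <- make_aln("ACG", "ACG", "ACG")
  expect_length(build_triplet_profile(a, 1, 2, 3)$pos, 0L)

  # hand enumeration of AAAA/AACC/ACCC: col1 AAA skip; col2 A,A,C -> ab;
  # col3 A,C,C -> bc; col4 A,C,C -> bc
  b <- make_aln("AAAA", "AACC", "ACCC")
  pr <- build_triplet_profile(b, 1, 2, 3)
  expect_equal(pr$pos, c(1L, 2L, 3L))
  expect_equal(pr$pattern, c(1L, 3L, 3L))

  # (A,A,C) pattern 'ab'; gaps and 3-way-distinct are skipped
  d <- make_aln("AT-C", "AGAC", "CCAC")
  pr2 <- build_triplet_profile(d, 1, 2, 3)
  expect_equal(pr2$pos, 0L)              # col1 A,A,C only informative site
  expect_equal(pr2$pattern, 1L)
  expect_error(build_triplet_profile(make_aln("AC", "AG"), 1, 2, 2))
})

test_that("binomial tail matches the closed form for an all-minor window", {
  prof <- structure(list(triplet = 1:3, names = paste0("s", 1:3),
                         pos = 0:19, pattern = rep(2L, 20L), aln_len = 20L),
                    class = "triplet_profile")
  res <- scan_triplet(prof, scan_config(window = 20, alpha = 0.5),
                      background = c(ab = 0.5, ac = 0.5, bc = 0.5))
  expect_equal(nrow(res), 1L)
  expect_equal(res$p_raw, 0.5^20, tolerance = 1e-12)
  expect_equal(res$p_raw, 9.5367e-7, tolerance = 1e-4)
})

test_that("windows shorter than the profile are skipped with a warning", {
  a <- random_aln(3, 40, 7)
  prof <- build_triplet_profile(a, 1, 2, 3)
  expect_warning(res <- scan_triplet(prof, scan_config(window = 1000)),
                 "skipped")
  expect_equal(nrow(res), 0L)
})

test_that("breakpoint demarcation follows the midpoint and terminus rules", {
  prof <- structure(list(triplet = 1:3, names = paste0("s", 1:3),
                         pos = c(10L, 90L, 100L, 150L, 200L, 260L),
                         pattern = c(1L, 1L, 2L, 2L, 2L, 1L),
                         aln_len = 300L),
                    class = "triplet_profile")
  region <- data.frame(pattern = "ac", begin_idx = 3L, end_idx = 5L)
  bp <- demarcate_breakpoints(region, prof)
  expect_equal(bp[["begin"]], 95L)        # floor((90+100)/2)
  expect_equal(bp[["end"]], 231L)         # floor((200+260)/2)+1

  # region reaching the first informative site -> alignment start
  region0 <- data.frame(pattern = "ab", begin_idx = 1L, end_idx = 2L)
  prof0 <- prof; prof0$pattern <- c(1L, 1L, 2L, 2L, 2L, 2L)
  expect_equal(demarcate_breakpoints(region0, prof0)[["begin"]], 0L)
})

test_that("identical sequences yield an empty event table with the contract columns", {
  a <- make_aln("ACGTACGT", "ACGTACGT", "ACGTACGT", "ACGTACGT")
  ev <- scan_all(a)
  expect_s3_class(ev, "recomb_events")
  expect_equal(nrow(ev), 0L)
  expect_true(all(c("recombinant", "major_parent", "minor_parent", "begin",
                    "end", "p_raw", "p_corrected", "flags", "method")
                  %in% names(ev)))
  expect_error(scan_all(make_aln("AC", "AC")), "at least 3")
})

test_that("bonferroni factor is the triplet count times window placements", {
  # 5 sequences: one divergent mosaic so at least one region survives
  set.seed(5)
  sim <- mosaic_dataset(11, n_taxa = 5, len = 4000, ev_len = 1200)
  a <- sim$alignment
  cfg <- scan_config()
  ev <- scan_all(a, cfg)
  expect_gt(nrow(ev), 0L)
  # recompute the factor for the exemplar's triplet by hand
  e <- ev[1, ]
  prof <- build_triplet_profile(a, e$recombinant, e$major_parent,
                                e$minor_parent)
  placements <- length(prof$pos) - cfg$window + 1L
  factor <- choose(5, 3) * placements
  expect_equal(e$p_corrected, min(1, e$p_raw * factor), tolerance = 1e-12)
})

test_that("a single implanted mosaic is recovered inside its true interval", {
  sim <- mosaic_dataset(21)
  ev <- scan_all(sim$alignment)
  tr <- sim$truth
  hit <- which(ev$recombinant == tr$acceptor &
               pmin(ev$end, tr$end) > pmax(ev$begin, tr$begin))
  expect_gte(length(hit), 1L)
  h <- hit[1L]
  # informative-site span of the exemplar lies within the tract +- slack
  expect_lt(abs(ev$begin[h] - tr$begin), 120)
  expect_lt(abs(ev$end[h] - tr$end), 120)
  expect_equal(ev$minor_parent[h], tr$donor)
})

test_that("event tables are deterministic and order-invariant up to names", {
  sim <- mosaic_dataset(31, n_taxa = 8, len = 5000)
  a <- sim$alignment
  ev1 <- scan_all(a)
  ev2 <- scan_all(a)
  expect_identical(ev1, ev2)
  # permute sequence order: coordinates and p-values unchanged
  perm <- sample(seq_len(n_seq(a)))
  b <- structure(list(names = a$names[perm],
                      mat = a$mat[perm, , drop = FALSE]),
                 class = "alignment")
  ev3 <- scan_all(b)
  key <- function(e) e[order(e$recombinant, e$begin),
                       c("recombinant", "begin", "end", "p_raw")]
  expect_equal(key(ev3), key(ev1), ignore_attr = TRUE)
})

test_that("reported events always satisfy the p-value invariants", {
  sim <- mosaic_dataset(41, n_taxa = 8, len = 6000)
  ev <- scan_all(sim$alignment)
  expect_true(all(ev$p_corrected >= ev$p_raw))
  expect_true(all(ev$p_corrected < 0.05))
  expect_true(all(ev$begin < ev$end))
  expect_true(all(ev$recombinant != ev$major_parent &
                  ev$recombinant != ev$minor_parent))
})

test_that("consolidation keeps the lowest-p exemplar of reciprocal-overlap groups", {
  ev <- structure(data.frame(
    recombinant = c("x", "x", "x", "y"),
    major_parent = "m", minor_parent = "n",
    begin = c(100L, 120L, 500L, 100L), end = c(300L, 310L, 700L, 300L),
    p_raw = c(1e-8, 1e-10, 1e-6, 1e-4),
    p_corrected = c(1e-5, 1e-7, 1e-3, 1e-2),
    flags = "", method = "triplet_scan", stringsAsFactors = FALSE),
    class = c("recomb_events", "data.frame"))
  out <- consolidate_events(ev)
  expect_equal(nrow(out), 3L)              # overlapping x-pair merged
  expect_true(1e-7 %in% out$p_corrected)   # exemplar = min p member
  expect_false(1e-5 %in% out$p_corrected)
})

test_that("event CSV uses 1-based inclusive coordinates", {
  ev <- structure(data.frame(
    recombinant = "x", major_parent = "m", minor_parent = "n",
    begin = 10L, end = 20L, p_raw = 1e-9, p_corrected = 1e-6,
    flags = "", method = "triplet_scan", stringsAsFactors = FALSE),
    class = c("recomb_events", "data.frame"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_event_table(ev, f)
  df <- read.csv(f)
  expect_equal(df$begin_1based, 11L)
  expect_equal(df$end_1based, 20L)
})
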