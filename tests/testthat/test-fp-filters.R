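# Pair incompatibility, PHI permutation test, Hudson-Kaplan Rm, vetting.

test_that("pair incompatibility reproduces the classic gamete cases", {
  three <- make_aln("AA", "AC", "CA", "CA")     # gametes 00,01,10
  expect_equal(pair_incompatibility(three, 1, 2), 0L)
  four <- make_aln("AA", "AC", "CA", "CC")      # all four gametes
  expect_equal(pair_incompatibility(four, 1, 2), 1L)
  mono <- make_aln("AA", "AC", "AA")
  expect_true(is.na(pair_incompatibility(mono, 1, 2)))
  # symmetric in column order
  a <- random_aln(6, 10, 3)
  expect_equal(pair_incompatibility(a, 2, 7), pair_incompatibility(a, 7, 2))
})

test_that("pair incompatibility equals exhaustive Fitch extra mutations", {
  set.seed(17)
  for (rep in 1:40) {
    n <- sample(4:6, 1)
    si <- sample(c("A", "C", "G")[seq_len(sample(2:3, 1))], n, replace = TRUE)
    sj <- sample(c("A", "C", "T")[seq_len(sample(2:3, 1))], n, replace = TRUE)
    if (length(unique(si)) < 2 || length(unique(sj)) < 2) next
    a <- alignment(paste0("t", 1:n), matrix(c(si, sj), ncol = 2))
    expect_equal(pair_incompatibility(a, 1, 2),
                 fitch_pair_oracle(si, sj),
                 info = paste(si, collapse = ""), ignore_attr = TRUE)
  }
})

test_that("incompatibility is zero for all pairs of a tree-compatible alignment", {
  a <- compatible_aln(8, 40, seed = 2)
  cols <- which(as.character(classify_sites(a)$class) != "invariant")
  for (i in head(cols, 8)) {
    for (j in tail(cols, 8)) {
      if (i < j) {
        s <- pair_incompatibility(a, i, j)
        if (!is.na(s)) expect_equal(s, 0L)
      }
    }
  }
})

test_that("PHI is zero without homoplasy and its p-value follows the formula", {
  a <- compatible_aln(10, 60, seed = 3)
  res <- phi_test(a, w = 60, n_perm = 50, seed = 1)
  expect_equal(res$phi, 0)
  res0 <- phi_test(a, w = 60, n_perm = 0, seed = 1)
  expect_equal(res0$p_perm, 1)              # (1+0)/(0+1)
  expect_gte(res$p_perm, 1 / (res$n_perm + 1))
  expect_error(phi_test(make_aln("AC", "AC", "AC"), seed = 1),
               "insufficient")
  expect_error(phi_test(a, n_perm = 10), "seed")
})

test_that("PHI is invariant to row order and column reversal", {
  sim <- simulate_clonal(10, 1500, 0.05, seed = 9)
  a <- sim$alignment
  r1 <- phi_test(a, n_perm = 100, seed = 4)
  perm <- rev(seq_len(n_seq(a)))
  b <- structure(list(names = a$names[perm],
                      mat = a$mat[perm, , drop = FALSE]), class = "alignment")
  r2 <- phi_test(b, n_perm = 100, seed = 4)
  expect_equal(r2$phi, r1$phi)
  rev_a <- structure(list(names = a$names,
                          mat = a$mat[, rev(seq_len(aln_length(a)))]),
                     class = "alignment")
  r3 <- phi_test(rev_a, n_perm = 100, seed = 4)
  expect_equal(r3$phi, r1$phi)
})

test_that("PHI detects an implanted mosaic", {
  sim <- mosaic_dataset(77, n_taxa = 10, len = 4000, ev_len = 1200)
  res <- phi_test(sim$alignment, n_perm = 500, seed = 2)
  expect_lt(res$p_perm, 0.05)
})

test_that("Rm reproduces the textbook cases", {
  a <- make_aln("AA", "AC", "CA", "CC")
  r <- hudson_kaplan_rm(a)
  expect_equal(r$rm, 1L)
  expect_equal(nrow(r$incompatible_pairs), 1L)
  expect_equal(hudson_kaplan_rm(compatible_aln(8, 30, 5))$rm, 0L)
})

test_that("Rm equals the exhaustive interval-subset optimum on random alignments", {
  set.seed(23)
  for (rep in 1:40) {
    a <- random_aln(sample(4:8, 1), sample(8:12, 1), seed = 1000 + rep)
    r <- hudson_kaplan_rm(a)
    expect_equal(r$rm, max_disjoint_oracle(r$incompatible_pairs))
  }
})

test_that("Rm never decreases when sequences are added (biallelic sites)", {
  # binary-state columns: every segregating site stays biallelic in all
  # subsets, so the four-gamete pair set can only grow with more rows
  set.seed(55)
  for (rep in 1:5) {
    mat <- matrix(sample(c("A", "C"), 8 * 12, replace = TRUE), 8, 12)
    a <- alignment(paste0("s", 1:8), mat)
    rms <- vapply(4:8, function(k) {
      hudson_kaplan_rm(aln_subset(a, seq_len(k)))$rm
    }, integer(1))
    expect_true(all(diff(rms) >= 0L))
  }
})

test_that("an event over an all-gap block is flagged as possible misalignment", {
  sim <- simulate_clonal(8, 800, 0.05, seed = 12)
  a <- sim$alignment
  a$mat[, 301:320] <- "-"                  # 20-column all-gap block
  ev <- structure(data.frame(
    recombinant = "t1", major_parent = "t2", minor_parent = "t3",
    begin = 280L, end = 340L, p_raw = 1e-9, p_corrected = 1e-6,
    flags = "", method = "triplet_scan", stringsAsFactors = FALSE),
    class = c("recomb_events", "data.frame"))
  out <- vet_event(ev, a, vet_config(n_perm = 50, seed = 1))
  expect_match(out$flags, "misalignment_suspect")
})

test_that("a genuine implanted event passes vetting and a fake one does not", {
  sim <- mosaic_dataset(88, n_taxa = 10, len = 6000, ev_len = 1500)
  tr <- sim$truth
  ev <- scan_all(sim$alignment)
  h <- which(ev$recombinant == tr$acceptor)[1]
  out <- vet_event(ev[h, , drop = FALSE], sim$alignment,
                   vet_config(n_perm = 200, seed = 3))
  expect_identical(out$flags, "")
  # pseudo-event on a clonal alignment should trip at least one check
  cl <- simulate_clonal(10, 5000, 0.05, seed = 99)
  fake <- ev[h, , drop = FALSE]
  fake$recombinant <- "t1"; fake$major_parent <- "t2"
  fake$minor_parent <- "t3"; fake$begin <- 2000L; fake$end <- 2600L
  out2 <- vet_event(fake, cl$alignment, vet_config(n_perm = 200, seed = 3))
  expect_gt(nchar(out2$flags), 0)
  expect_error(vet_event({f <- fake; f$end <- 99999L; f}, cl$alignment),
               "outside")
})

test_that("a tiny vetting sub-alignment records phi_untestable", {
  a <- make_aln("ACGTACGTAAGG", "ACGAACGTAAGG", "ACGTACGAAAGG")
  ev <- structure(data.frame(
    recombinant = "s1", major_parent = "s2", minor_parent = "s3",
    begin = 2L, end = 8L, p_raw = 1e-4, p_corrected = 1e-3,
    flags = "", method = "triplet_scan", stringsAsFactors = FALSE),
    class = c("recomb_events", "data.frame"))
  out <- vet_event(ev, a, vet_config(n_perm = 20, seed = 1))
  expect_match(out$method, "phi_untestable")
})
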