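# Alignment container, file round trips, site classification, identity.

test_that("alignment construction normalizes and validates", {
  a <- alignment(c("s1", "s2"), c("acgu", "ACG?"))
  expect_equal(aln_strings(a), c(s1 = "ACGT", s2 = "ACGN"))
  expect_error(alignment(c("x", "x"), c("AC", "AC")), "duplicate")
  expect_error(alignment(c("a", "b"), c("ACG", "AC")), "ragged")
  expect_error(alignment("a", "AXG"), "column 2")
  expect_error(alignment(character(), character()), "at least one")
})

test_that("single-record FASTA parses and a normalized file round-trips byte-identically", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACGT"), f)
  a <- read_alignment(f, "fasta")
  expect_equal(a$names, "s1")
  expect_equal(aln_strings(a), c(s1 = "ACGT"))
  expect_equal(aln_length(a), 4L)

  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a1", "ACGTACGTACGT", ">a2", "ACGAACGAACGA",
               ">a3", "TTGTACGTACGA"), f2)
  out <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(read_alignment(f2), out, "fasta")
  expect_identical(readLines(out), readLines(f2))
})

test_that("interleaved and sequential PHYLIP parse to the hand-built matrix", {
  f <- withr::local_tempfile(fileext = ".phy")
  writeLines(c("2 8", "s1 ACGT", "s2 ACGA", "ACGT", "ACGA"), f)
  a <- read_alignment(f, "phylip")
  expect_equal(aln_strings(a), c(s1 = "ACGTACGT", s2 = "ACGAACGA"))

  f2 <- withr::local_tempfile(fileext = ".phy")
  writeLines(c(" 3 6", "alpha ACGTAC", "beta  ACGTAA", "gamma TTGTAC"), f2)
  b <- read_alignment(f2, "auto")          # digits sniffed as phylip
  expect_equal(b$names, c("alpha", "beta", "gamma"))
  expect_equal(unname(aln_strings(b)[3]), "TTGTAC")
})

test_that("round trips are the identity for all three formats on random alignments", {
  for (seed in 1:5) {
    a <- random_aln(4, 30, seed, gap_frac = 0.05)
    for (fmt in c("fasta", "phylip", "nexus")) {
      f <- withr::local_tempfile()
      write_alignment(a, f, fmt)
      b <- read_alignment(f, fmt)
      expect_equal(b$names, a$names, info = fmt)
      expect_equal(aln_strings(b), aln_strings(a), info = fmt)
    }
  }
})

test_that("write_alignment refuses an empty alignment", {
  a <- make_aln("ACGT", "ACGA")
  a$mat <- a$mat[integer(), , drop = FALSE]; a$names <- character()
  expect_error(write_alignment(a, tempfile(), "fasta"), "empty")
})

test_that("site classification covers every column and applies the missing threshold", {
  a <- make_aln("AAAG", "AACG", "ACC-", "ACCG")
  cl <- classify_sites(a, max_missing_frac = 0.2)
  expect_equal(as.character(cl$class),
               c("invariant", "biallelic_informative", "biallelic_singleton",
                 "gapped_excluded"))
  expect_equal(cl$minor_count[2], 2L)
  # partition property: each column exactly one class
  b <- random_aln(6, 50, 99, gap_frac = 0.1)
  cl2 <- classify_sites(b)
  expect_equal(nrow(cl2), 50L)
  expect_false(anyNA(cl2$class))
})

test_that("pairwise identity excludes gap columns and is symmetric", {
  a <- make_aln("ACGT", "ACGA", "AC-T")
  expect_equal(pairwise_identity(a, 1, 2), 0.75)
  expect_equal(pairwise_identity(a, 1, 3), 1.0)     # 3 comparable, all equal
  expect_equal(pairwise_identity(a, 1, 2), pairwise_identity(a, 2, 1))
  expect_error(pairwise_identity(a, 2, 2), "self-comparison")
  expect_error(pairwise_identity(a, 1, 2, c(2, 2)), "window")
  # invariant under appending all-gap columns
  b <- alignment(a$names, paste0(aln_strings(a), "--"))
  expect_equal(pairwise_identity(b, 1, 2), pairwise_identity(a, 1, 2))
  # no comparable columns -> NA
  z <- make_aln("A-", "-A")
  expect_true(is.na(pairwise_identity(z, 1, 2)))
})

test_that("GFF3 and GenBank annotations convert to 0-based half-open intervals", {
  g <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr\tsrc\tgene\t1\t9\t.\t+\t.\tID=geneA",
               "chr\tsrc\tCDS\t1\t6\t.\t+\t0\tID=cdsA1;Parent=geneA",
               "chr\tsrc\tCDS\t10\t15\t.\t+\t0\tID=cdsA2;Parent=geneA"), g)
  tr <- read_annotation(g, "gff3")
  gene <- tr[tr$type == "gene", ]
  expect_equal(c(gene$start, gene$end), c(0L, 9L))
  cds <- tr[tr$type == "CDS", ]
  expect_equal(cds$start, c(0L, 9L))
  expect_equal(cds$end, c(6L, 15L))

  gb <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("FEATURES             Location/Qualifiers",
               "     gene            complement(4..9)",
               '                     /gene="orfB"',
               "     CDS             complement(4..9)",
               '                     /gene="orfB"',
               "//"), gb)
  tb <- read_annotation(gb, "genbank")
  expect_equal(tb$strand, rep("-", 2))
  expect_equal(tb$start[1], 3L)
  expect_equal(tb$end[1], 9L)
  # coordinate validation against the alignment length
  expect_error(read_annotation(gb, "genbank", aln_len = 8), "beyond")
})

test_that("GenBank join locations keep transcription order per strand", {
  gb <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("FEATURES             Location/Qualifiers",
               "     CDS             join(1..6,10..15)",
               '                     /gene="orfA"',
               "     CDS             complement(join(21..26,30..35))",
               '                     /gene="orfC"'), gb)
  tb <- read_annotation(gb, "genbank")
  a <- tb[tb$feature_id == "orfA", ]
  expect_equal(a$start, c(0L, 9L))       # ascending for '+'
  c_ <- tb[tb$feature_id == "orfC", ]
  expect_equal(c_$start, c(29L, 20L))    # descending for '-'
})
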