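# Fixtures built in code: small alignments, random matrices, and
# tree-compatible (homoplasy-free) alignments for the incompatibility null.

make_aln <- function(..., names = NULL) {
  seqs <- c(...)
  if (is.null(names)) names <- paste0("s", seq_along(seqs))
  alignment(names, seqs)
}

# Random gap-free alignment over ACGT.
random_aln <- function(n, L, seed, gap_frac = 0) {
  set.seed(seed)
  chars <- sample(c("A", "C", "G", "T"), n * L, replace = TRUE)
  if (gap_frac > 0) {
    gp <- sample(c(TRUE, FALSE), n * L, replace = TRUE,
                 prob = c(gap_frac, 1 - gap_frac))
    chars[gp] <- "-"
  }
  alignment(paste0("s", seq_len(n)), matrix(chars, nrow = n))
}

# Alignment whose variable columns are clade indicators of one fixed tree
# (each column = exactly one mutation on one branch): no homoplasy is
# possible, every column pair is compatible.
compatible_aln <- function(n_taxa = 8, n_sites = 40, seed = 1) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa)
  tips <- tr$tip.label
  clades <- lapply((n_taxa + 2):(n_taxa + tr$Nnode), function(nd) {
    ape::extract.clade(tr, nd)$tip.label
  })
  clades <- c(clades, as.list(tips))      # terminal-branch mutations too
  mat <- matrix("A", n_taxa, n_sites, dimnames = list(tips, NULL))
  for (j in seq_len(n_sites)) {
    cl <- clades[[sample.int(length(clades), 1L)]]
    mat[cl, j] <- "C"
  }
  alignment(tips, mat)
}

# Minimum extra mutations for a two-column character pair by exhaustive
# Fitch parsimony over every unrooted topology (phangorn oracle).
fitch_pair_oracle <- function(states_i, states_j) {
  taxa <- paste0("t", seq_along(states_i))
  dat <- rbind(states_i, states_j)
  colnames(dat) <- taxa
  lv <- sort(unique(c(states_i, states_j)))
  pd <- phangorn::phyDat(t(dat), type = "USER", levels = lv)
  trees <- phangorn::allTrees(length(taxa), rooted = FALSE, tip.label = taxa)
  best <- min(phangorn::parsimony(trees, pd))
  floor_score <- (length(unique(states_i)) - 1L) +
                 (length(unique(states_j)) - 1L)
  best - floor_score
}

# Maximum number of pairwise non-overlapping intervals, by exhaustive
# recursion over interval choices (memoized on the remaining start bound).
max_disjoint_oracle <- function(intervals) {
  if (!nrow(intervals)) return(0L)
  memo <- new.env()
  solve <- function(from) {
    key <- as.character(from)
    if (!is.null(memo[[key]])) return(memo[[key]])
    cand <- which(intervals[, 1L] >= from)
    best <- 0L
    for (k in cand) {
      best <- max(best, 1L + solve(intervals[k, 2L]))
    }
    memo[[key]] <- best
    best
  }
  solve(-1L)
}

# One mosaic dataset at the standard study conditions.
mosaic_dataset <- function(seed, n_taxa = 10, len = 10000, ev_len = 1500,
                           div = 0.15, parent_div = 0.10) {
  cl <- simulate_clonal(n_taxa, len, div, seed = seed)
  im <- implant_events(cl$alignment, 1, ev_len, ev_len, parent_div,
                       seed = seed)
  list(alignment = im$alignment, truth = im$truth, tree = cl$tree)
}
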