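# Fixture generator: clonal alignments evolved on random Yule trees under
# Jukes-Cantor (optionally with discrete-gamma rate heterogeneity), and
# mosaic recombinants implanted with exact ground truth.

#' Simulate a clonal (recombination-free) alignment
#'
#' Draws a random Yule tree (`ape::rphylo`, pure birth), rescales branch
#' lengths so the mean root-to-tip path equals `mean_divergence`
#' (expected substitutions per site), and evolves sequences root-to-tip
#' under Jukes-Cantor with independent sites and multiple hits allowed
#' (`phangorn::simSeq`). Optional discrete-gamma rate heterogeneity is
#' applied by assigning sites to equal-probability rate categories.
#' Fully deterministic under `seed`.
#'
#' @param n_taxa Number of sequences (>= 2).
#' @param length Alignment length in columns.
#' @param mean_divergence Expected root-to-tip substitutions per site; 0
#'   yields identical rows equal to the random root sequence.
#' @param seed RNG seed.
#' @param gamma_shape Optional shape of a discrete-gamma (4 categories)
#'   site-rate distribution; `NULL` (default) for homogeneous rates.
#' @return List with `alignment` (an [alignment()]) and `tree` (newick
#'   string; taxa `t1..tn`).
#' @export
simulate_clonal <- function(n_taxa, length, mean_divergence, seed,
                            gamma_shape = NULL) {
  if (n_taxa < 2L) stop("n_taxa must be at least 2")
  set.seed(as.integer(seed))
  tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
  tree$tip.label <- paste0("t", seq_len(n_taxa))
  depths <- ape::node.depth.edgelength(tree)[seq_len(n_taxa)]
  if (mean_divergence > 0) {
    tree$edge.length <- tree$edge.length * mean_divergence / mean(depths)
  } else {
    tree$edge.length[] <- 0
  }
  if (is.null(gamma_shape)) {
    mm <- toupper(as.character(phangorn::simSeq(tree, l = length,
                                                type = "DNA")))
    mat <- mm[tree$tip.label, , drop = FALSE]
  } else {
    rates <- discrete_gamma_rates(gamma_shape, 4L)
    cat_of <- sample.int(4L, length, replace = TRUE)
    mat <- matrix("", n_taxa, length,
                  dimnames = list(tree$tip.label, NULL))
    for (k in 1:4) {
      cols <- which(cat_of == k)
      if (!length(cols)) next
      mm <- toupper(as.character(phangorn::simSeq(tree, l = length(cols),
                                                  type = "DNA",
                                                  rate = rates[k])))
      mat[, cols] <- mm[tree$tip.label, , drop = FALSE]
    }
  }
  aln <- alignment(tree$tip.label, mat)
  list(alignment = aln, tree = ape::write.tree(tree))
}

# Means of the 4 equal-probability discrete-gamma categories (mean 1).
discrete_gamma_rates <- function(shape, k = 4L) {
  q <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = shape,
                     rate = shape)
  r <- vapply(seq_len(k), function(i) {
    # category mean via the incomplete-gamma identity
    (stats::pgamma(q[i + 1L], shape + 1, rate = shape) -
     stats::pgamma(q[i], shape + 1, rate = shape)) * k
  }, numeric(1L))
  r / mean(r)
}

#' Implant mosaic recombination events with ground truth
#'
#' For each event a donor/acceptor pair with p-distance at least
#' `min_parent_divergence` is drawn, an interval length uniform in
#' `[min_len, max_len]` is placed uniformly along the alignment, and the
#' donor's columns are copied into the acceptor. Events never overlap
#' within an acceptor. Ground truth is exact by construction.
#'
#' @param aln A clonal [alignment()].
#' @param n_events Number of events to implant.
#' @param min_len,max_len Event length bounds in columns.
#' @param min_parent_divergence Minimum donor/acceptor p-distance.
#' @param seed RNG seed.
#' @return List with `alignment` (mosaic) and `truth` (data frame:
#'   `acceptor`, `donor`, `begin`, `end`, 0-based half-open).
#' @export
implant_events <- function(aln, n_events, min_len, max_len,
                           min_parent_divergence, seed) {
  stopifnot(is_alignment(aln), min_len <= max_len,
            max_len <= aln_length(aln))
  set.seed(as.integer(seed))
  truth <- data.frame(acceptor = character(), donor = character(),
                      begin = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (n_events == 0L) return(list(alignment = aln, truth = truth))
  n <- n_seq(aln)
  pd <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pd[i, j] <- pd[j, i] <- p_distance(aln, i, j)
    }
  }
  elig <- which(pd >= min_parent_divergence & upper.tri(pd), arr.ind = TRUE)
  if (!nrow(elig)) {
    stop("infeasible: no sequence pair reaches parent divergence ",
         min_parent_divergence)
  }
  mat <- aln$mat
  placed <- vector("list", n)          # occupied intervals per acceptor
  for (e in seq_len(n_events)) {
    done <- FALSE
    for (try in seq_len(200L)) {
      pick <- elig[sample.int(nrow(elig), 1L), ]
      # orient randomly: either member may act as donor
      if (stats::runif(1) < 0.5) pick <- rev(pick)
      donor <- pick[[1L]]; acceptor <- pick[[2L]]
      len <- min_len + sample.int(max_len - min_len + 1L, 1L) - 1L
      begin <- sample.int(aln_length(aln) - len + 1L, 1L) - 1L
      end <- begin + len
      clash <- any(vapply(placed[[acceptor]], function(iv) {
        begin < iv[2L] && end > iv[1L]
      }, logical(1L)))
      if (!clash) { done <- TRUE; break }
    }
    if (!done) stop("infeasible: could not place non-overlapping event ", e)
    mat[acceptor, (begin + 1L):end] <- mat[donor, (begin + 1L):end]
    placed[[acceptor]] <- c(placed[[acceptor]], list(c(begin, end)))
    truth <- rbind(truth, data.frame(acceptor = aln$names[acceptor],
                                     donor = aln$names[donor],
                                     begin = begin, end = end,
                                     stringsAsFactors = FALSE))
  }
  list(alignment = structure(list(names = aln$names, mat = mat),
                             class = "alignment"),
       truth = truth)
}

#' Write simulator outputs
#'
#' FASTA alignment, truth TSV (`acceptor`, `donor`, `begin_1based`,
#' `end_1based`) and newick tree.
#'
#' @param sim Result of [simulate_clonal()] after [implant_events()]
#'   (list with `alignment`, `truth`, optionally `tree`).
#' @param dir Output directory (created if absent).
#' @param prefix File name prefix (default `"sim"`).
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_alignment(sim$alignment, file.path(dir, paste0(prefix, ".fasta")),
                  "fasta")
  if (!is.null(sim$truth)) {
    tt <- sim$truth
    tt$begin_1based <- tt$begin + 1L
    tt$end_1based <- tt$end
    utils::write.table(tt[, c("acceptor", "donor", "begin_1based",
                              "end_1based")],
                       file.path(dir, paste0(prefix, ".truth.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(sim$tree)) {
    writeLines(sim$tree, file.path(dir, paste0(prefix, ".nwk")))
  }
  invisible(NULL)
}
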