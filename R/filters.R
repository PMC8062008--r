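# False-positive vetting: pairwise homoplasy index (PHI) permutation test,
# Hudson-Kaplan four-gamete lower bound Rm, and a gap-density misalignment
# heuristic, applied per dataset or per detected event.

# Integer-encode columns: A,C,G,T -> 1..4, everything else 0 (missing).
encode_columns <- function(aln, cols = seq_len(aln_length(aln))) {
  m <- aln$mat[, cols, drop = FALSE]
  enc <- match(m, ALN_BASES)
  enc[is.na(enc)] <- 0L
  matrix(as.integer(enc), nrow = nrow(m))
}

# Parsimony-informative columns: >= 2 non-missing states, each of at least
# two states carried by >= 2 sequences.
informative_columns <- function(aln) {
  enc <- encode_columns(aln)
  which(apply(enc, 2L, function(v) {
    tab <- tabulate(v[v > 0L], nbins = 4L)
    sum(tab >= 2L) >= 2L
  }))
}

#' Refined incompatibility score of a column pair
#'
#' For two alignment columns, over the sequences unambiguous at both, the
#' score is `E - V + Cc` where `V` is the total number of states observed
#' at the two columns, `E` the number of distinct joint state pairs and
#' `Cc` the number of connected components of the bipartite state graph.
#' This equals the minimum number of extra mutations (beyond the parsimony
#' floor) that any tree must invoke to explain the pair; 0 means the pair
#' is compatible with some tree, and for a biallelic pair a score of 1 is
#' the classic four-gamete incompatibility.
#'
#' @param aln An [alignment()].
#' @param i,j Column indices (1-based).
#' @return Non-negative integer, or `NA` when either column is monomorphic
#'   after pairwise deletion of missing data.
#' @export
pair_incompatibility <- function(aln, i, j) {
  stopifnot(is_alignment(aln))
  enc <- encode_columns(aln, c(i, j))
  s <- pair_score_cpp(enc[, 1L], enc[, 2L])
  if (s < 0L) NA_integer_ else s
}

# Full m x m incompatibility matrix over the given columns.
incompatibility_matrix <- function(aln, cols) {
  incompat_matrix_cpp(encode_columns(aln, cols))
}

#' Pairwise homoplasy index (PHI) permutation test
#'
#' PHI is the mean refined incompatibility over all pairs of
#' parsimony-informative sites lying within `w` alignment columns of each
#' other. Recombination concentrates incompatibility among nearby sites, so
#' the observed PHI is compared against permutations that shuffle the
#' informative-column contents while keeping the positions fixed; the
#' p-value is the fraction of permutations with PHI at or below the
#' observed value (small p = evidence of recombination).
#'
#' @param aln An [alignment()].
#' @param w Proximity window in alignment columns (default 100).
#' @param n_perm Number of permutations (default 1000); 0 gives p = 1.
#' @param seed RNG seed (mandatory for reproducibility).
#' @return A `phi_result` list: `phi`, `n_pairs`, `n_informative`,
#'   `p_perm`, `n_perm`.
#' @export
phi_test <- function(aln, w = 100L, n_perm = 1000L, seed) {
  stopifnot(is_alignment(aln))
  if (missing(seed)) stop("'seed' is required")
  cols <- informative_columns(aln)
  m <- length(cols)
  pos <- cols - 1L
  pairs <- which(outer(pos, pos, function(x, y) y - x) <= w &
                 upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  if (m < 2L || nrow(pairs) < 2L) {
    stop("insufficient data: fewer than 2 informative-site pairs within w = ", w)
  }
  M <- incompatibility_matrix(aln, cols)
  sc <- M[pairs]
  usable <- !is.na(sc)
  if (!any(usable)) stop("insufficient data: no scorable site pairs")
  phi_obs <- mean(sc[usable])
  pa <- pairs[usable, 1L]; pb <- pairs[usable, 2L]
  set.seed(as.integer(seed))
  hits <- 0L
  for (b in seq_len(n_perm)) {
    pm <- sample.int(m)
    if (mean(M[cbind(pm[pa], pm[pb])], na.rm = TRUE) <= phi_obs) {
      hits <- hits + 1L
    }
  }
  structure(list(phi = phi_obs, n_pairs = sum(usable), n_informative = m,
                 p_perm = (1 + hits) / (n_perm + 1), n_perm = n_perm),
            class = "phi_result")
}

#' @export
print.phi_result <- function(x, ...) {
  cat(sprintf("PHI = %.5f  (pairs = %d, informative sites = %d)\n",
              x$phi, x$n_pairs, x$n_informative))
  cat(sprintf("permutation p = %.5g  (%d permutations)\n", x$p_perm, x$n_perm))
  invisible(x)
}

#' Hudson-Kaplan lower bound on the number of recombination events
#'
#' Collects all biallelic column pairs exhibiting all four gametes (missing
#' data dropped pairwise), removes any interval containing another, and
#' counts a maximal set of pairwise non-overlapping remaining intervals
#' greedily by right endpoint. That count, Rm, is a lower bound on the
#' number of recombination events in the sample's history.
#'
#' @param aln An [alignment()].
#' @return An `rm_result` list: `rm` and `incompatible_pairs` (two-column
#'   matrix of 0-based column positions, one row per four-gamete pair).
#' @export
hudson_kaplan_rm <- function(aln) {
  stopifnot(is_alignment(aln))
  enc <- encode_columns(aln)
  biall <- which(apply(enc, 2L, function(v) {
    length(unique(v[v > 0L])) == 2L
  }))
  pairs <- matrix(integer(), 0L, 2L)
  if (length(biall) >= 2L) {
    M <- incompat_matrix_cpp(enc[, biall, drop = FALSE])
    idx <- which(upper.tri(M) & !is.na(M) & M >= 1L, arr.ind = TRUE)
    if (nrow(idx)) {
      pairs <- cbind(biall[idx[, 1L]] - 1L, biall[idx[, 2L]] - 1L)
      pairs <- pairs[order(pairs[, 2L], pairs[, 1L]), , drop = FALSE]
    }
  }
  rm_count <- 0L
  if (nrow(pairs)) {
    # delete intervals that contain another interval: an interval is
    # non-minimal iff some other interval starts no earlier and ends no
    # later; one suffix-minimum sweep over the start-sorted list finds
    # them without the quadratic pairwise check
    uniq <- unique(pairs)
    ord <- order(uniq[, 1L], uniq[, 2L])
    st <- uniq[ord, 1L]; en <- uniq[ord, 2L]
    k <- length(st)
    suf_min_en <- rev(cummin(rev(en)))
    later_inside <- c(suf_min_en[-1L] <= en[-k], FALSE)
    same_start_before <- c(FALSE, st[-k] == st[-1L])  # smaller end sorts first
    keep <- !(later_inside | same_start_before)
    iv <- cbind(st[keep], en[keep])
    # greedy by right endpoint; intervals are open (i, j): overlap requires
    # sharing an internal segment, so the next interval may start at the
    # previous right endpoint
    last_end <- -1L
    for (u in order(iv[, 2L], iv[, 1L])) {
      if (iv[u, 1L] >= last_end) {
        rm_count <- rm_count + 1L
        last_end <- iv[u, 2L]
      }
    }
  }
  structure(list(rm = rm_count, incompatible_pairs = pairs),
            class = "rm_result")
}

#' Vetting configuration
#'
#' @param k Nearest neighbours (by global identity) added to the triplet
#'   for per-event testing (default 5).
#' @param pad Columns added on each side of the event region; `NULL`
#'   (default) uses the region length.
#' @param alpha Significance level for the per-event PHI test (default 0.05).
#' @param gap_frac Gap fraction across the triplet within the region above
#'   which the event is flagged as possible misalignment (default 0.3).
#' @param gaprun Length of a >=50%-gapped column run that triggers the
#'   misalignment flag when overlapped (default 15).
#' @param w,n_perm PHI test parameters (defaults 100, 1000).
#' @param seed RNG seed for the PHI permutations.
#' @export
vet_config <- function(k = 5L, pad = NULL, alpha = 0.05, gap_frac = 0.3,
                       gaprun = 15L, w = 100L, n_perm = 1000L, seed = 1L) {
  structure(list(k = as.integer(k), pad = pad, alpha = alpha,
                 gap_frac = gap_frac, gaprun = as.integer(gaprun),
                 w = as.integer(w), n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "vet_config")
}

#' Vet one detected event for false-positive signatures
#'
#' Three checks on the event neighbourhood (the triplet plus its `k`
#' nearest neighbours by global identity, over the region padded on both
#' sides): (a) `phi_suspect` when the PHI test fails to find recombination
#' evidence there (p > alpha); (b) `four_gamete_suspect` when no
#' four-gamete-incompatible site pair straddles either breakpoint;
#' (c) `misalignment_suspect` when the triplet gap fraction inside the
#' region exceeds `gap_frac` or the region overlaps a run of `gaprun`
#' consecutive columns each at least half gapped.
#'
#' @param event One-row `recomb_events` data frame.
#' @param aln The scanned [alignment()].
#' @param cfg A [vet_config()].
#' @return The event row with its `flags` (semicolon-separated) and `method`
#'   fields updated.
#' @export
vet_event <- function(event, aln, cfg = vet_config()) {
  stopifnot(is_alignment(aln))
  begin <- event$begin; end <- event$end
  if (!(begin >= 0L && end <= aln_length(aln) && begin < end)) {
    stop("event coordinates outside alignment")
  }
  trip <- c(event$recombinant, event$major_parent, event$minor_parent)
  trip_idx <- match(trip, aln$names)
  if (anyNA(trip_idx)) stop("event names a sequence absent from the alignment")
  flags <- character()
  pad <- if (is.null(cfg$pad)) end - begin else cfg$pad
  lo <- max(0L, begin - pad); hi <- min(aln_length(aln), end + pad)

  # (a) PHI on the triplet + k nearest neighbours over the padded region
  others <- setdiff(seq_len(n_seq(aln)), trip_idx)
  if (length(others)) {
    prox <- vapply(others, function(o) {
      mean(vapply(trip_idx, function(ti)
        pairwise_identity(aln, ti, o), numeric(1L)), na.rm = TRUE)
    }, numeric(1L))
    nb <- others[order(-prox)][seq_len(min(cfg$k, length(others)))]
  } else nb <- integer()
  sub <- aln_subset(aln, sort(c(trip_idx, nb)), (lo + 1L):hi)
  method <- event$method
  if (n_seq(sub) < 4L) {
    method <- paste0(method, ":phi_untestable")
  } else {
    phi <- tryCatch(phi_test(sub, w = cfg$w, n_perm = cfg$n_perm,
                             seed = cfg$seed),
                    error = function(e) NULL)
    if (is.null(phi)) {
      method <- paste0(method, ":phi_untestable")
    } else if (phi$p_perm > cfg$alpha) {
      flags <- c(flags, "phi_suspect")
    }
  }

  # (b) four-gamete pairs straddling a breakpoint (in sub-alignment space)
  rmres <- hudson_kaplan_rm(sub)
  straddles <- FALSE
  if (nrow(rmres$incompatible_pairs)) {
    pp <- rmres$incompatible_pairs + lo        # back to alignment columns
    for (b in c(begin, end)) {
      if (any(pp[, 1L] < b & pp[, 2L] >= b)) straddles <- TRUE
    }
  }
  if (!straddles) flags <- c(flags, "four_gamete_suspect")

  # (c) gap-density misalignment heuristic
  reg_cols <- (begin + 1L):end
  trip_block <- aln$mat[trip_idx, reg_cols, drop = FALSE]
  gapf <- mean(trip_block == "-")
  gap_col_frac <- colMeans(aln$mat == "-")
  heavy <- gap_col_frac >= 0.5
  r <- rle(heavy)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  bad_runs <- which(r$values & r$lengths >= cfg$gaprun)
  overlaps_run <- any(vapply(bad_runs, function(k) {
    run_start[k] <= end && run_end[k] > begin
  }, logical(1L)))
  if (gapf > cfg$gap_frac || overlaps_run) {
    flags <- c(flags, "misalignment_suspect")
  }

  event$flags <- paste(flags, collapse = ";")
  event$method <- method
  event
}

#' Vet every event of a table
#' @param events A `recomb_events` table.
#' @param aln The scanned [alignment()].
#' @param cfg A [vet_config()].
#' @return The table with flags updated.
#' @export
vet_events <- function(events, aln, cfg = vet_config()) {
  if (!nrow(events)) return(events)
  for (i in seq_len(nrow(events))) {
    events[i, ] <- vet_event(events[i, , drop = FALSE], aln, cfg)
  }
  events
}
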