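# Per-partition distance trees: Jukes-Cantor corrected distances and
# neighbour-joining topologies. Maximum-likelihood inference is
# deliberately out of scope; NJ + JC keeps the recombination-aware tree
# output light and exactly testable, and users can hand partitions to an
# external ML tool.

#' Jukes-Cantor distance matrix
#'
#' `d = -3/4 * log(1 - 4p/3)` on the pairwise-deletion p-distance.
#' Saturated pairs (`p >= 0.75`) receive the `cap` value; pairs with no
#' comparable columns get `NA` with a warning.
#'
#' @param aln An [alignment()].
#' @param cap Saturation marker in substitutions/site (default 5.0).
#' @return Symmetric numeric matrix with zero diagonal, dimnames = sequence
#'   names.
#' @export
jc_distance_matrix <- function(aln, cap = 5.0) {
  stopifnot(is_alignment(aln))
  n <- n_seq(aln)
  d <- matrix(0, n, n, dimnames = list(aln$names, aln$names))
  for (i in seq_len(max(0L, n - 1L))) {
    for (j in (i + 1L):n) {
      p <- p_distance(aln, i, j)
      v <- if (is.na(p)) {
        warning("no comparable columns between ", aln$names[i], " and ",
                aln$names[j])
        NA_real_
      } else if (p >= 0.75) cap
      else -0.75 * log(1 - 4 * p / 3)
      d[i, j] <- d[j, i] <- v
    }
  }
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard neighbour joining (Saitou-Nei Q-criterion via `ape::nj`).
#' Negative branch lengths are clamped to zero with the deficit
#' transferred to the sister branch so path lengths are preserved. Two- and
#' three-taxon inputs are solved in closed form. Output is an unrooted
#' newick string with 6-decimal branch lengths.
#'
#' @param dist Symmetric distance matrix with dimnames, or `dist` object.
#' @param names Optional taxon names overriding dimnames.
#' @return Newick string.
#' @export
nj_tree <- function(dist, names = NULL) {
  d <- as.matrix(dist)
  if (!is.null(names)) dimnames(d) <- list(names, names)
  nm <- rownames(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 taxa")
  fmt <- function(x) sprintf("%.6f", max(0, x))
  if (n == 2L) {
    return(paste0("(", nm[1L], ":", fmt(d[1L, 2L] / 2), ",", nm[2L], ":",
                  fmt(d[1L, 2L] / 2), ");"))
  }
  if (n == 3L) {
    x <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
    y <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
    z <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
    return(paste0("(", nm[1L], ":", fmt(x), ",", nm[2L], ":", fmt(y), ",",
                  nm[3L], ":", fmt(z), ");"))
  }
  tr <- ape::nj(d)
  tr <- clamp_negative_edges(tr)
  ape::write.tree(tr, digits = 6)
}

# Zero out negative edges, moving the deficit onto the sister edge (the
# other child of the same parent node) so root-to-tip path sums change as
# little as possible.
clamp_negative_edges <- function(tr) {
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1L]
    sisters <- setdiff(which(tr$edge[, 1L] == parent), e)
    if (length(sisters)) {
      s <- sisters[1L]
      tr$edge.length[s] <- max(0, tr$edge.length[s] + deficit)
    }
  }
  tr
}

#' Neighbour-joining trees per alignment partition
#'
#' One JC + NJ tree per partition with at least `min_sites` columns;
#' shorter partitions are skipped and listed.
#'
#' @param parts A [partition_alignment()] result.
#' @param min_sites Minimum partition width (default 100).
#' @return List with `trees` (named list of newick strings, names
#'   `<begin>-<end>` 1-based inclusive) and `skipped` (character vector of
#'   interval names too short to analyse).
#' @export
trees_per_partition <- function(parts, min_sites = 100L) {
  trees <- list(); skipped <- character()
  for (k in seq_along(parts$partitions)) {
    iv <- parts$table[k, ]
    key <- paste0(iv$begin_1based, "-", iv$end_1based)
    sub <- parts$partitions[[k]]
    if (aln_length(sub) < min_sites) {
      skipped <- c(skipped, key)
      next
    }
    trees[[key]] <- nj_tree(jc_distance_matrix(sub))
  }
  list(trees = trees, skipped = skipped)
}
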