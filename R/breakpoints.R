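# Breakpoint-distribution tests against annotation-derived column
# partitions, plus a sliding-window breakpoint density table.

#' Collect breakpoint positions from an event table
#'
#' Each event contributes its begin and end breakpoint unless that
#' breakpoint sits at an alignment terminus (column 0 or the alignment
#' length), where demarcation was truncated rather than observed.
#'
#' @param events A `recomb_events` table.
#' @param aln_len Alignment length in columns.
#' @param collapse_per_event If `TRUE`, each event contributes at most one
#'   position (its interval midpoint) instead of both edges.
#' @return Sorted integer vector of 0-based columns (class
#'   `breakpoint_set`), with the originating event rows as attribute
#'   `source_events`.
#' @export
breakpoint_positions <- function(events, aln_len, collapse_per_event = FALSE) {
  if (collapse_per_event) {
    pos <- (events$begin + events$end) %/% 2L
    src <- seq_len(nrow(events))
  } else {
    pos <- c(events$begin, events$end)
    src <- rep(seq_len(nrow(events)), 2L)
  }
  ok <- pos > 0L & pos < aln_len
  structure(sort(as.integer(pos[ok])), source_events = src[ok][order(pos[ok])],
            class = "breakpoint_set")
}

#' Partition alignment columns by annotation
#'
#' Three labelling schemes over `[0, aln_len)`:
#' `coding_vs_noncoding` labels columns by CDS membership;
#' `per_gene` labels by gene id with an `intergenic` fallback (columns in
#' overlapping genes go to the gene with the nearest start, ties broken
#' lexicographically, recorded in the `overlap_resolution` attribute);
#' `edge_vs_interior` labels the first and last
#' `ceiling(edge_frac * gene length)` columns of each gene `edge`, the
#' remaining gene columns `interior`, everything else `intergenic`.
#'
#' @param annotation An `annotation_track`.
#' @param aln_len Alignment length in columns.
#' @param scheme Partition scheme.
#' @param edge_frac Fraction of gene length treated as edge per terminus
#'   (default 0.1).
#' @return Character vector of per-column labels (class
#'   `region_partition`, attribute `scheme`).
#' @export
partition_columns <- function(annotation, aln_len,
                              scheme = c("coding_vs_noncoding", "per_gene",
                                         "edge_vs_interior"),
                              edge_frac = 0.1) {
  scheme <- match.arg(scheme)
  ann <- as.data.frame(annotation)
  if (nrow(ann) && any(ann$end > aln_len)) {
    stop("annotation extends beyond alignment length")
  }
  genes <- gene_spans(ann)
  labels <- switch(scheme,
    coding_vs_noncoding = {
      lab <- rep("noncoding", aln_len)
      cds <- ann[ann$type == "CDS", , drop = FALSE]
      for (r in seq_len(nrow(cds))) {
        lab[(cds$start[r] + 1L):cds$end[r]] <- "coding"
      }
      lab
    },
    per_gene = {
      lab <- rep("intergenic", aln_len)
      owner <- rep(NA_character_, aln_len)
      owner_start <- rep(NA_integer_, aln_len)
      resolutions <- character()
      for (r in seq_len(nrow(genes))) {
        cols <- (genes$start[r] + 1L):genes$end[r]
        clash <- !is.na(owner[cols])
        take <- !clash
        if (any(clash)) {
          cc <- cols[clash]
          d_new <- abs((cc - 1L) - genes$start[r])
          d_old <- abs((cc - 1L) - owner_start[cc])
          win <- d_new < d_old |
            (d_new == d_old & genes$feature_id[r] < owner[cc])
          take[clash] <- win
          resolutions <- c(resolutions,
                           paste0(genes$feature_id[r], " vs ",
                                  unique(owner[cc]), ": ", sum(win),
                                  " columns reassigned"))
        }
        owner[cols[take]] <- genes$feature_id[r]
        owner_start[cols[take]] <- genes$start[r]
      }
      lab[!is.na(owner)] <- owner[!is.na(owner)]
      attr(lab, "overlap_resolution") <- resolutions
      lab
    },
    edge_vs_interior = {
      lab <- rep("intergenic", aln_len)
      for (r in seq_len(nrow(genes))) {
        glen <- genes$end[r] - genes$start[r]
        e <- ceiling(edge_frac * glen)
        cols <- (genes$start[r] + 1L):genes$end[r]
        lab[cols] <- "interior"
        lab[cols[seq_len(min(e, glen))]] <- "edge"
        lab[cols[glen - seq_len(min(e, glen)) + 1L]] <- "edge"
      }
      lab
    })
  structure(labels, scheme = scheme, class = "region_partition")
}

# One span per gene: union extent of 'gene' rows, falling back to CDS
# extents for features annotated only as CDS.
gene_spans <- function(ann) {
  g <- ann[ann$type == "gene", , drop = FALSE]
  if (!nrow(g)) g <- ann[ann$type == "CDS", , drop = FALSE]
  if (!nrow(g)) {
    return(data.frame(feature_id = character(), start = integer(),
                      end = integer()))
  }
  sp <- split(g, g$feature_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(feature_id = d$feature_id[1L], start = min(d$start),
               end = max(d$end))
  }))
  out[order(out$start, out$feature_id), , drop = FALSE]
}

#' Permutation test of breakpoint counts per region label
#'
#' Null model: breakpoints fall independently and uniformly over all
#' alignment columns. For each label the observed count is compared with
#' the permutation distribution two-tailed by distance from the null mean;
#' Benjamini-Hochberg adjusted p-values are added across labels.
#'
#' @param bps A [breakpoint_positions()] result (0-based columns).
#' @param part A [partition_columns()] result.
#' @param n_perm Number of permutations (default 10000).
#' @param seed RNG seed.
#' @return Data frame: `label`, `span_columns`, `observed`,
#'   `expected_mean`, `p`, `p_BH`.
#' @export
breakpoint_region_test <- function(bps, part, n_perm = 10000L, seed = 1L) {
  if (!length(bps)) stop("breakpoint set is empty")
  len <- length(part)
  labs <- levels(factor(part))
  span <- as.integer(table(factor(part, levels = labs)))
  drop <- span == 0L
  labs <- labs[!drop]; span <- span[!drop]
  nb <- length(bps)
  obs <- as.integer(table(factor(part[bps + 1L], levels = labs)))
  expected <- nb * span / len
  lab_f <- factor(part, levels = labs)
  set.seed(as.integer(seed))
  extreme <- integer(length(labs))
  obs_dev <- abs(obs - expected)
  for (b in seq_len(n_perm)) {
    cnt <- tabulate(as.integer(lab_f)[sample.int(len, nb, replace = TRUE)],
                    nbins = length(labs))
    extreme <- extreme + as.integer(abs(cnt - expected) >= obs_dev)
  }
  p <- (1 + extreme) / (n_perm + 1)
  data.frame(label = labs, span_columns = span, observed = obs,
             expected_mean = expected, p = p,
             p_BH = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}

#' Sliding-window breakpoint density table
#'
#' @param bps A [breakpoint_positions()] result (0-based columns).
#' @param aln_len Alignment length.
#' @param window Window width in columns (default 200).
#' @param step Step in columns (default 50); must not exceed `window`.
#' @return Data frame: `center_1based`, `count`, `partial` (TRUE for the
#'   trailing window truncated at the alignment end).
#' @export
breakpoint_density <- function(bps, aln_len, window = 200L, step = 50L) {
  stopifnot(window >= step, step >= 1L)
  starts <- seq(0L, max(0L, aln_len - window), by = step)
  if (starts[length(starts)] + window < aln_len) {
    starts <- c(starts, starts[length(starts)] + step)
  }
  ends <- pmin(starts + window, aln_len)
  partial <- ends < starts + window
  counts <- vapply(seq_along(starts), function(k) {
    sum(bps >= starts[k] & bps < ends[k])
  }, integer(1L))
  data.frame(center_1based = (starts + ends) %/% 2L + 1L, count = counts,
             partial = partial)
}
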