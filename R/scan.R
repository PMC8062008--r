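# Triplet sliding-window recombination scan: windowed informative-site
# profiles, binomial significance with a leave-window-out background,
# Bonferroni correction, breakpoint demarcation by flanking-site midpoints,
# and cross-triplet event consolidation.

#' Scan configuration
#'
#' Tuning parameters of the triplet scan. The window is measured in
#' triplet-informative sites (not alignment columns) so that sensitivity is
#' comparable across divergence levels.
#'
#' @param window Window size in informative sites (default 30).
#' @param step Window step in informative sites (default 1).
#' @param alpha Family-wise significance level (default 0.05).
#' @param min_event_len Minimum informative sites per event (default 3).
#' @param bonferroni_factor_mode `"triplets_x_windows"` (default,
#'   conservative: number of triplets times window placements in the
#'   triplet) or `"triplets_only"`.
#' @param max_missing_frac Per-column missing-data threshold used by site
#'   classification (default 0.2).
#' @param seed RNG seed reserved for tie randomization; unused by the
#'   default deterministic tie-breaks.
#' @return A `scan_config` list.
#' @export
scan_config <- function(window = 30L, step = 1L, alpha = 0.05,
                        min_event_len = 3L,
                        bonferroni_factor_mode = c("triplets_x_windows",
                                                   "triplets_only"),
                        max_missing_frac = 0.2, seed = 1L) {
  bonferroni_factor_mode <- match.arg(bonferroni_factor_mode)
  stopifnot(window >= min_event_len, min_event_len >= 1L,
            alpha > 0, alpha < 1, step >= 1L)
  structure(list(window = as.integer(window), step = as.integer(step),
                 alpha = alpha, min_event_len = as.integer(min_event_len),
                 bonferroni_factor_mode = bonferroni_factor_mode,
                 max_missing_frac = max_missing_frac,
                 seed = as.integer(seed)),
            class = "scan_config")
}

PATTERNS <- c("ab", "ac", "bc")

#' Build the informative-site profile of a triplet
#'
#' A column is triplet-informative when all three rows are unambiguous,
#' ungapped bases and exactly two of them share a state (a 2-vs-1 split);
#' 3-way-identical and 3-way-distinct columns carry no signal and are
#' skipped. The profile records, per informative column, which pair agrees
#' (`ab`, `ac` or `bc`).
#'
#' @param aln An [alignment()] with at least 3 sequences.
#' @param a,b,c Distinct row indices (1-based) or sequence names.
#' @return A `triplet_profile`: list with `triplet` (indices), `names`,
#'   `pos` (0-based informative columns, increasing), `pattern` (agreeing
#'   pair per column) and `aln_len`.
#' @export
build_triplet_profile <- function(aln, a, b, c) {
  stopifnot(is_alignment(aln))
  if (n_seq(aln) < 3L) stop("alignment must contain at least 3 sequences")
  idx <- c(a, b, c)
  if (is.character(idx)) idx <- match(idx, aln$names)
  if (anyNA(idx)) stop("unknown sequence name in triplet")
  if (anyDuplicated(idx)) stop("triplet members must be distinct")
  ra <- aln$mat[idx[1L], ]; rb <- aln$mat[idx[2L], ]; rc <- aln$mat[idx[3L], ]
  ok <- is_base(ra) & is_base(rb) & is_base(rc)
  pat <- integer(length(ra))                 # 0 = uninformative
  eq_ab <- ra == rb; eq_ac <- ra == rc; eq_bc <- rb == rc
  pat[ok & eq_ab & !eq_ac] <- 1L
  pat[ok & eq_ac & !eq_ab] <- 2L
  pat[ok & eq_bc & !eq_ab & !eq_ac] <- 3L
  keep <- which(pat > 0L)
  structure(list(triplet = idx, names = aln$names[idx],
                 pos = keep - 1L, pattern = pat[keep],
                 aln_len = aln_length(aln)),
            class = "triplet_profile")
}

#' Scan one triplet for pattern-clustered windows
#'
#' Slides a window of `cfg$window` informative sites along the profile. In
#' each window and for each agreeing-pair pattern the binomial upper tail
#' of the in-window pattern count is computed against a background
#' proportion estimated from all informative sites of the triplet outside
#' the current window (with a small continuity correction keeping it off 0
#' and 1). Windows significant after Bonferroni correction are merged into
#' maximal runs per pattern and trimmed to the first/last in-run site
#' carrying the pattern.
#'
#' @param profile A [build_triplet_profile()] result.
#' @param cfg A [scan_config()].
#' @param background Optional fixed per-pattern background proportions
#'   (named numeric over `ab`, `ac`, `bc`); by default the leave-window-out
#'   estimate is used.
#' @param n_triplets Number of triplets in the family-wise correction
#'   (default 1; [scan_all()] passes `choose(n, 3)`).
#' @return Data frame of candidate regions: `pattern`, `begin_idx`,
#'   `end_idx` (informative-site indices), `begin_pos`, `end_pos` (0-based
#'   columns of the first/last in-region pattern site), `p_raw`, `factor`.
#' @export
scan_triplet <- function(profile, cfg = scan_config(), background = NULL,
                         n_triplets = 1L) {
  m <- length(profile$pos)
  W <- cfg$window
  empty <- data.frame(pattern = character(), begin_idx = integer(),
                      end_idx = integer(), begin_pos = integer(),
                      end_pos = integer(), p_raw = numeric(),
                      factor = numeric())
  if (m < W) {
    warning("triplet has ", m, " informative sites < window ", W, "; skipped")
    return(empty)
  }
  starts <- seq(1L, m - W + 1L, by = cfg$step)
  n_windows <- length(starts)
  factor <- switch(cfg$bonferroni_factor_mode,
                   triplets_x_windows = as.numeric(n_triplets) * n_windows,
                   triplets_only = as.numeric(n_triplets))
  out <- list()
  for (q in 1:3) {
    is_q <- as.integer(profile$pattern == q)
    tot_q <- sum(is_q)
    cs <- c(0L, cumsum(is_q))
    wq <- cs[starts + W] - cs[starts]       # in-window count of pattern q
    if (!is.null(background)) {
      phat <- rep(background[[PATTERNS[q]]], n_windows)
    } else {
      # leave-window-out with Haldane continuity correction
      phat <- (tot_q - wq + 0.5) / (m - W + 1)
    }
    p_raw <- stats::pbinom(wq - 1L, W, phat, lower.tail = FALSE)
    sig <- which(p_raw * factor < cfg$alpha)
    if (!length(sig)) next
    # merge overlapping significant windows into maximal runs
    s <- starts[sig]
    brk <- which(diff(s) >= W)              # gap: windows no longer overlap
    run_first <- c(1L, brk + 1L)
    run_last <- c(brk, length(s))
    for (r in seq_along(run_first)) {
      sigrun <- sig[run_first[r]:run_last[r]]
      # anchor on the most significant window of the run: its first
      # pattern site seeds the maximal contiguous pattern run, which is
      # the demarcated tract (inside a transferred fragment every
      # informative site supports the donor pair, so the fragment spans a
      # single uninterrupted run)
      s_best <- starts[sigrun[which.min(p_raw[sigrun])]]
      qin <- which(is_q[s_best:(s_best + W - 1L)] == 1L)
      if (!length(qin)) next
      bi <- ei <- s_best + qin[1L] - 1L
      while (bi > 1L && is_q[bi - 1L] == 1L) bi <- bi - 1L
      while (ei < m && is_q[ei + 1L] == 1L) ei <- ei + 1L
      # chance occurrences of the pattern just outside the tract inflate
      # the run by a geometric number of sites per edge; trim the expected
      # overshoot given the background pattern frequency
      run_len <- ei - bi + 1L
      p_bg <- (tot_q - sum(is_q[bi:ei]) + 0.5) / (m - run_len + 1L)
      overshoot <- as.integer(round(p_bg / (1 - p_bg)))
      if (overshoot > 0L && run_len - 2L * overshoot >= cfg$min_event_len) {
        bi <- bi + overshoot
        ei <- ei - overshoot
        while (is_q[bi] == 0L && bi < ei) bi <- bi + 1L
        while (is_q[ei] == 0L && ei > bi) ei <- ei - 1L
      }
      if (ei - bi + 1L < cfg$min_event_len) next
      pmin_run <- min(p_raw[sig[run_first[r]:run_last[r]]])
      out[[length(out) + 1L]] <- data.frame(
        pattern = PATTERNS[q], begin_idx = bi, end_idx = ei,
        begin_pos = profile$pos[bi], end_pos = profile$pos[ei],
        p_raw = pmin_run, factor = factor)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$begin_idx, res$pattern), , drop = FALSE]
}

#' Demarcate breakpoints of a candidate region
#'
#' The left breakpoint is the floor midpoint between the last informative
#' site before the region that supports a background (non-region) pattern
#' and the first in-region site; the right breakpoint likewise. Where no
#' flanking informative site exists the alignment terminus is used.
#'
#' @param region One row of a [scan_triplet()] result.
#' @param profile The matching `triplet_profile`.
#' @return Integer `(begin, end)`, 0-based half-open alignment columns.
#' @export
demarcate_breakpoints <- function(region, profile) {
  q <- match(region$pattern, PATTERNS)
  bi <- region$begin_idx; ei <- region$end_idx
  left_bg <- which(profile$pattern[seq_len(bi - 1L)] != q)
  begin <- if (length(left_bg)) {
    (profile$pos[max(left_bg)] + profile$pos[bi]) %/% 2L
  } else 0L
  right_rel <- which(profile$pattern[-seq_len(ei)] != q)
  end <- if (length(right_rel)) {
    (profile$pos[ei] + profile$pos[ei + min(right_rel)]) %/% 2L + 1L
  } else profile$aln_len
  c(begin = as.integer(begin), end = as.integer(end))
}

# Resolve recombinant / parents for a region within its triplet.
# The in-region agreeing pair is {recombinant, minor parent}. Which of the
# two carries the transferred fragment is decided by the identity-change
# discriminator: the recombinant is the pair member whose identity to the
# third triplet member changes across the region boundary (its in-region
# sequence is foreign), while the untouched member's identity to the third
# is flat. The major parent is the remaining member closest to the
# recombinant outside the region. When the pattern shows no switch at all
# (the outside majority equals the in-region pattern) the odd member out
# is reported with an "ambiguous_recombinant" marker.
resolve_triplet_roles <- function(region, profile, aln) {
  q <- match(region$pattern, PATTERNS)
  pair_members <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  inside <- pair_members[[q]]
  out_mask <- seq_along(profile$pattern) < region$begin_idx |
              seq_along(profile$pattern) > region$end_idx
  cnt <- tabulate(profile$pattern[out_mask], nbins = 3L)
  cnt[q] <- -1L                           # a switched pattern must exist
  ambiguous <- all(cnt <= 0L)
  bp <- demarcate_breakpoints(region, profile)
  if (!ambiguous) {
    z <- setdiff(1:3, inside)
    shift <- vapply(inside, function(mm) {
      inside_id <- pairwise_identity(aln, profile$triplet[mm],
                                     profile$triplet[z],
                                     c(bp[["begin"]], bp[["end"]]))
      outside_id <- outside_identity(aln, profile$triplet[mm],
                                     profile$triplet[z], bp)
      if (is.na(inside_id)) 0 else abs(inside_id - outside_id)
    }, numeric(1L))
    if (shift[1L] != shift[2L]) {
      rec <- inside[which.max(shift)]
    } else {
      # tie: fall back to the partner-switch reading of the outside majority
      outside <- pair_members[[which.max(cnt)]]
      rec <- intersect(inside, outside)
    }
    minor <- setdiff(inside, rec)
    major <- setdiff(1:3, c(rec, minor))
  } else {
    rec <- setdiff(1:3, inside)
    # rank the two pair members by identity to the recombinant outside the
    # region: the closer one plays major parent
    ids <- vapply(inside, function(mm) {
      outside_identity(aln, profile$triplet[rec], profile$triplet[mm], bp)
    }, numeric(1L))
    major <- inside[which.max(ids)]
    minor <- setdiff(inside, major)
  }
  list(recombinant = profile$names[rec], major = profile$names[major],
       minor = profile$names[minor], ambiguous = ambiguous)
}

outside_identity <- function(aln, i, j, bp) {
  len <- aln_length(aln)
  vals <- c(if (bp[1L] > 0L) pairwise_identity(aln, i, j, c(0L, bp[1L])),
            if (bp[2L] < len) pairwise_identity(aln, i, j, c(bp[2L], len)))
  if (!length(vals) || all(is.na(vals))) return(0)
  mean(vals, na.rm = TRUE)
}

#' Exhaustive triplet scan of an alignment
#'
#' Scans all `choose(n, 3)` triplets with [scan_triplet()], converts
#' surviving regions to recombination events (recombinant = the triplet
#' member whose closest partner switches inside vs outside the region),
#' and consolidates events across triplets: events naming the same
#' recombinant whose intervals overlap reciprocally by at least 50% are
#' grouped, and the lowest-`p_corrected` exemplar represents each group
#' (ties by smaller begin, then lexicographic recombinant name).
#'
#' @param aln An [alignment()] of at least 3 sequences.
#' @param cfg A [scan_config()].
#' @return An event table (class `recomb_events`): data frame with columns
#'   `recombinant`, `major_parent`, `minor_parent`, `begin`, `end` (0-based
#'   half-open), `p_raw`, `p_corrected`, `flags`, `method`.
#' @export
scan_all <- function(aln, cfg = scan_config()) {
  stopifnot(is_alignment(aln))
  n <- n_seq(aln)
  if (n < 3L) stop("scan requires at least 3 sequences")
  triplets <- utils::combn(n, 3L)
  n_tri <- ncol(triplets)
  evs <- list()
  for (t in seq_len(n_tri)) {
    prof <- build_triplet_profile(aln, triplets[1L, t], triplets[2L, t],
                                  triplets[3L, t])
    regions <- suppressWarnings(scan_triplet(prof, cfg, n_triplets = n_tri))
    for (r in seq_len(nrow(regions))) {
      evs[[length(evs) + 1L]] <- region_to_event(regions[r, ], prof, aln, cfg)
    }
  }
  consolidate_events(event_table(evs))
}

region_to_event <- function(region, profile, aln, cfg) {
  bp <- demarcate_breakpoints(region, profile)
  roles <- resolve_triplet_roles(region, profile, aln)
  method <- paste0("triplet_scan",
                   if (roles$ambiguous) ":ambiguous_recombinant" else "")
  p_corr <- min(1, region$p_raw * region$factor)
  data.frame(recombinant = roles$recombinant, major_parent = roles$major,
             minor_parent = roles$minor, begin = bp[["begin"]],
             end = bp[["end"]], p_raw = region$p_raw, p_corrected = p_corr,
             flags = "", method = method, stringsAsFactors = FALSE)
}

event_table <- function(rows) {
  if (!length(rows)) {
    rows <- list(data.frame(recombinant = character(),
                            major_parent = character(),
                            minor_parent = character(), begin = integer(),
                            end = integer(), p_raw = numeric(),
                            p_corrected = numeric(), flags = character(),
                            method = character(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  class(df) <- c("recomb_events", "data.frame")
  df
}

reciprocal_overlap <- function(b1, e1, b2, e2) {
  ov <- pmax(0L, pmin(e1, e2) - pmax(b1, b2))
  ov >= 0.5 * (e1 - b1) & ov >= 0.5 * (e2 - b2)
}

#' Consolidate events across triplets
#'
#' Union-find grouping of events that name the same recombinant and whose
#' intervals overlap reciprocally by at least 50%; each group is reported
#' by its minimum-`p_corrected` member (ties: smaller begin, then
#' lexicographic recombinant).
#'
#' @param events A `recomb_events` table.
#' @return Consolidated `recomb_events` table, sorted by `p_corrected`.
#' @export
consolidate_events <- function(events) {
  n <- nrow(events)
  if (n <= 1L) return(events)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  ord <- order(events$recombinant, events$begin)
  for (u in seq_len(n - 1L)) {
    i <- ord[u]
    for (v in (u + 1L):n) {
      j <- ord[v]
      if (events$recombinant[j] != events$recombinant[i]) break
      if (reciprocal_overlap(events$begin[i], events$end[i],
                             events$begin[j], events$end[j])) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  grp <- vapply(seq_len(n), find, integer(1L))
  keep <- vapply(split(seq_len(n), grp), function(ix) {
    o <- order(events$p_corrected[ix], events$begin[ix],
               events$recombinant[ix])
    ix[o[1L]]
  }, integer(1L))
  out <- events[sort(keep), , drop = FALSE]
  out <- out[order(out$p_corrected, out$begin, out$recombinant), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("recomb_events", "data.frame")
  out
}

#' Write an event table as CSV
#'
#' Columns: recombinant, major_parent, minor_parent, begin_1based,
#' end_1based (inclusive), p_raw, p_corrected, flags, method, plus any
#' extra columns present (e.g. parent groups from [query_scan()]).
#'
#' @param events A `recomb_events` table.
#' @param path Output path.
#' @export
write_event_table <- function(events, path) {
  df <- as.data.frame(events)
  df$begin_1based <- df$begin + 1L
  df$end_1based <- df$end                 # half-open 0-based == inclusive 1-based
  base_cols <- c("recombinant", "major_parent", "minor_parent",
                 "begin_1based", "end_1based", "p_raw", "p_corrected",
                 "flags", "method")
  extra <- setdiff(names(df), c(base_cols, "begin", "end"))
  utils::write.csv(df[, c(base_cols, extra), drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(NULL)
}
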