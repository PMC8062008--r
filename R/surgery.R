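# Recombination-free dataset construction: four surgery modes over a
# detected event table, plus codon-aware gene alignment extraction.

# Events used for surgery: suspect-flagged events are potential false
# positives and are excluded unless include_flagged.
surgery_events <- function(events, include_flagged = FALSE) {
  if (!nrow(events) || include_flagged) return(events)
  events[!nzchar(events$flags), , drop = FALSE]
}

#' Remove recombinant sequences
#'
#' Drops every sequence named as the recombinant of at least one event.
#' Events carrying suspect flags are ignored by default.
#'
#' @param aln An [alignment()].
#' @param events A `recomb_events` table.
#' @param include_flagged Use suspect-flagged events too (default FALSE).
#' @return The reduced [alignment()], row order preserved.
#' @export
strip_recombinants <- function(aln, events, include_flagged = FALSE) {
  stopifnot(is_alignment(aln))
  ev <- surgery_events(events, include_flagged)
  check_event_names(aln, events)
  drop <- unique(ev$recombinant)
  keep <- setdiff(aln$names, drop)
  if (length(keep) < 2L) {
    stop("removing ", length(drop), " recombinants would leave fewer than 2 sequences")
  }
  aln_subset(aln, keep)
}

check_event_names <- function(aln, events) {
  unknown <- setdiff(events$recombinant, aln$names)
  if (length(unknown)) {
    stop("event recombinant not in alignment: ",
         paste(unknown, collapse = ", "))
  }
}

#' Mask recombination-derived fragments
#'
#' Replaces the event region of each recombinant row by `missing_char`
#' (default `N`, so downstream phylogenetics treats the fragment as
#' unknown rather than deleted). Overlapping events union their masks; all
#' other rows and coordinates are untouched.
#'
#' @inheritParams strip_recombinants
#' @param missing_char Masking character, `"N"` or `"-"`.
#' @return The masked [alignment()].
#' @export
mask_recombinant_fragments <- function(aln, events, missing_char = "N",
                                       include_flagged = FALSE) {
  stopifnot(is_alignment(aln))
  if (!missing_char %in% ALN_CHARS) {
    stop("missing_char must be one of the allowed alignment characters")
  }
  ev <- surgery_events(events, include_flagged)
  check_event_names(aln, events)
  mat <- aln$mat
  for (i in seq_len(nrow(ev))) {
    mat[ev$recombinant[i], (ev$begin[i] + 1L):ev$end[i]] <- missing_char
  }
  structure(list(names = aln$names, mat = mat), class = "alignment")
}

#' Split recombinant sequences into constituent parts
#'
#' Each recombinant row is replaced by a backbone row (`name_bb`, event
#' regions masked) plus one row per event (`name_ev<k>`, only that event's
#' columns retained). Backbone and parts partition the original row: at
#' every column exactly one of them carries the original character.
#'
#' @inheritParams mask_recombinant_fragments
#' @return The expanded [alignment()].
#' @export
split_recombinants <- function(aln, events, missing_char = "N",
                               include_flagged = FALSE) {
  stopifnot(is_alignment(aln))
  if (!missing_char %in% ALN_CHARS) {
    stop("missing_char must be one of the allowed alignment characters")
  }
  ev <- surgery_events(events, include_flagged)
  check_event_names(aln, events)
  recs <- unique(ev$recombinant)
  out_names <- character(); out_rows <- list()
  used <- setdiff(aln$names, recs)
  uniquify <- function(nm) {
    i <- 0L; cand <- nm
    while (cand %in% c(used, out_names)) {
      i <- i + 1L
      cand <- paste0(nm, "_r", i)
      warning("name collision: using ", cand)
    }
    cand
  }
  for (nm in aln$names) {
    if (!nm %in% recs) {
      out_names <- c(out_names, nm)
      out_rows[[length(out_rows) + 1L]] <- aln$mat[nm, ]
      next
    }
    rows <- ev[ev$recombinant == nm, , drop = FALSE]
    rows <- rows[order(rows$begin), , drop = FALSE]
    bb <- aln$mat[nm, ]
    for (k in seq_len(nrow(rows))) {
      part <- rep(missing_char, aln_length(aln))
      cols <- (rows$begin[k] + 1L):rows$end[k]
      part[cols] <- aln$mat[nm, cols]
      bb[cols] <- missing_char
      out_names <- c(out_names, uniquify(paste0(nm, "_ev", k)))
      out_rows[[length(out_rows) + 1L]] <- part
    }
    out_names <- c(out_names, uniquify(paste0(nm, "_bb")))
    out_rows[[length(out_rows) + 1L]] <- bb
  }
  mat <- do.call(rbind, out_rows)
  rownames(mat) <- out_names
  structure(list(names = out_names, mat = mat), class = "alignment")
}

#' Partition an alignment at breakpoints
#'
#' Unique breakpoint columns split `[0, len)` into consecutive intervals;
#' one sub-alignment is returned per interval. Breakpoints at column 0 or
#' at the alignment length create no split and are dropped with a note.
#'
#' @param aln An [alignment()].
#' @param events_or_breakpoints A `recomb_events` table (both breakpoints
#'   of every unflagged event are used) or an integer vector of 0-based
#'   columns.
#' @param include_flagged Use suspect-flagged events too (default FALSE).
#' @return List with `partitions` (list of `alignment`s), `table` (data
#'   frame: `partition_id`, `begin_1based`, `end_1based`) and `dropped`
#'   (terminus breakpoints removed).
#' @export
partition_alignment <- function(aln, events_or_breakpoints,
                                include_flagged = FALSE) {
  stopifnot(is_alignment(aln))
  len <- aln_length(aln)
  x <- events_or_breakpoints
  bps <- if (is.data.frame(x)) {
    ev <- surgery_events(x, include_flagged)
    c(ev$begin, ev$end)
  } else as.integer(x)
  dropped <- bps[bps <= 0L | bps >= len]
  bps <- sort(unique(bps[bps > 0L & bps < len]))
  bounds <- c(0L, bps, len)
  parts <- list(); tab <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    cols <- (bounds[k] + 1L):bounds[k + 1L]
    parts[[k]] <- aln_subset(aln, cols = cols)
    tab[[k]] <- data.frame(partition_id = k, begin_1based = bounds[k] + 1L,
                           end_1based = bounds[k + 1L])
  }
  list(partitions = parts, table = do.call(rbind, tab),
       dropped = unique(dropped))
}

#' Extract per-gene alignments from annotation
#'
#' Splices the CDS intervals of each gene in transcription order,
#' reverse-complements minus-strand genes, honours the phase of the first
#' interval, and optionally (default) enforces codon integrity: the
#' trailing `length %% 3` columns are trimmed, and any codon in which some
#' row carries 1 or 2 gap characters (a frame-shifting partial codon) is
#' removed column-synchronized across all rows so the output stays
#' aligned. Columns covered by two or more CDS features in different
#' frames can be excluded.
#'
#' @param aln An [alignment()].
#' @param annotation An `annotation_track` with CDS features.
#' @param drop_partial_codons Trim to whole codons and drop frame-shifting
#'   gap codons (default TRUE).
#' @param exclude_overlap_frames Remove columns expressed in multiple
#'   reading frames (default FALSE).
#' @return Named list of gene [alignment()]s.
#' @export
extract_gene_alignments <- function(aln, annotation,
                                    drop_partial_codons = TRUE,
                                    exclude_overlap_frames = FALSE) {
  stopifnot(is_alignment(aln))
  ann <- as.data.frame(annotation)
  cds <- ann[ann$type == "CDS", , drop = FALSE]
  if (!nrow(cds)) stop("annotation contains no CDS features")
  if (any(cds$end > aln_length(aln))) {
    stop("CDS extends beyond alignment length")
  }
  overlap_excl <- integer()
  if (exclude_overlap_frames) {
    frame_of <- function(r, col) {
      offs <- (col - cds$start[r] - cds$phase[r]) %% 3L
      offs
    }
    cover <- vector("list", aln_length(aln))
    for (r in seq_len(nrow(cds))) {
      for (col in cds$start[r]:(cds$end[r] - 1L)) {
        cover[[col + 1L]] <- c(cover[[col + 1L]], frame_of(r, col))
      }
    }
    overlap_excl <- which(vapply(cover, function(f)
      length(unique(f)) > 1L, logical(1L))) - 1L
  }
  out <- list()
  for (gid in unique(cds$feature_id)) {
    rows <- cds[cds$feature_id == gid, , drop = FALSE]   # transcription order
    minus <- rows$strand[1L] == "-"
    cols <- unlist(lapply(seq_len(nrow(rows)), function(r) {
      cc <- rows$start[r]:(rows$end[r] - 1L)
      if (minus) rev(cc) else cc
    }))
    cols <- setdiff(cols, overlap_excl)
    phase0 <- rows$phase[1L]
    if (!is.na(phase0) && phase0 > 0L && length(cols) > phase0) {
      cols <- cols[-seq_len(phase0)]
    }
    mat <- aln$mat[, cols + 1L, drop = FALSE]
    if (minus) mat <- revcomp_matrix(mat)
    if (drop_partial_codons) {
      trim <- ncol(mat) %% 3L
      if (trim) mat <- mat[, seq_len(ncol(mat) - trim), drop = FALSE]
      if (ncol(mat)) {
        codon <- (seq_len(ncol(mat)) - 1L) %/% 3L
        bad <- vapply(unique(codon), function(cd) {
          block <- mat[, codon == cd, drop = FALSE]
          any(rowSums(block == "-") %% 3L != 0L)
        }, logical(1L))
        keep <- !(codon %in% (unique(codon)[bad]))
        mat <- mat[, keep, drop = FALSE]
      }
    }
    if (!ncol(mat)) {
      warning("gene ", gid, " empty after codon filtering; skipped")
      next
    }
    out[[gid]] <- structure(list(names = aln$names, mat = mat),
                            class = "alignment")
  }
  out
}

REVCOMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
             W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
             N = "N", "-" = "-")

revcomp_matrix <- function(mat) {
  # columns are already in transcription (reversed) order; complement only
  out <- matrix(REVCOMP[mat], nrow = nrow(mat))
  rownames(out) <- rownames(mat)
  out
}
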