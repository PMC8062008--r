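# Query-vs-reference scanning: designated query sequences are tested for
# recombination between designated (optionally grouped) references.

#' Assign query/reference roles to sequences
#'
#' Two designation rules. `tags`: a name containing the token `[Q]` is a
#' query; `[R]` or `[R:<group>]` is a reference (group defaults to
#' `"all"`); untagged names are ignored. `lists`: membership files (one
#' name per line; reference lines may append a whitespace-separated group)
#' decide, and a name in both files is an error.
#'
#' @param names Sequence names.
#' @param rule `"tags"` or `"lists"`.
#' @param query_list,ref_list File paths (lists mode).
#' @return A `role_assignment` data frame: `name`, `role` (query /
#'   reference / ignored), `group` (`NA` for non-references).
#' @export
assign_roles <- function(names, rule = c("tags", "lists"),
                         query_list = NULL, ref_list = NULL) {
  rule <- match.arg(rule)
  role <- rep("ignored", length(names))
  group <- rep(NA_character_, length(names))
  if (rule == "tags") {
    is_q <- grepl("[Q]", names, fixed = TRUE)
    has_r <- grepl("\\[R(:[^]]+)?\\]", names)
    if (any(is_q & has_r)) {
      stop("role conflict: sequence tagged both [Q] and [R]: ",
           names[is_q & has_r][1L])
    }
    role[is_q] <- "query"
    role[has_r] <- "reference"
    for (i in which(has_r)) {
      tag <- regmatches(names[i], regexpr("\\[R(:[^]]+)?\\]", names[i]))
      g <- sub("^\\[R:?([^]]*)\\]$", "\\1", tag)
      group[i] <- if (nzchar(g)) g else "all"
    }
  } else {
    if (is.null(query_list) || is.null(ref_list)) {
      stop("lists mode requires query_list and ref_list files")
    }
    ql <- trimws(readLines(query_list, warn = FALSE))
    ql <- ql[nzchar(ql)]
    rl_lines <- trimws(readLines(ref_list, warn = FALSE))
    rl_lines <- rl_lines[nzchar(rl_lines)]
    rl_parts <- strsplit(rl_lines, "\\s+")
    rl <- vapply(rl_parts, `[[`, "", 1L)
    rg <- vapply(rl_parts, function(p) if (length(p) > 1L) p[2L] else "all", "")
    both <- intersect(ql, rl)
    if (length(both)) {
      stop("role conflict: listed as both query and reference: ",
           paste(both, collapse = ", "))
    }
    role[names %in% ql] <- "query"
    ridx <- match(names, rl)
    role[!is.na(ridx)] <- "reference"
    group[!is.na(ridx)] <- rg[ridx[!is.na(ridx)]]
  }
  if (!any(role == "query")) stop("configuration error: zero query sequences")
  structure(data.frame(name = names, role = role, group = group,
                       stringsAsFactors = FALSE),
            class = c("role_assignment", "data.frame"))
}

# Eligible (r1, r2) reference pairs: cross-group when >1 group exists,
# otherwise all same-group pairs.
reference_pairs <- function(roles) {
  refs <- which(roles$role == "reference")
  if (length(refs) < 2L) {
    stop("configuration error: fewer than 2 eligible reference sequences")
  }
  grp <- roles$group[refs]
  pairs <- utils::combn(refs, 2L)
  if (length(unique(grp)) > 1L) {
    keep <- roles$group[pairs[1L, ]] != roles$group[pairs[2L, ]]
    pairs <- pairs[, keep, drop = FALSE]
    if (!ncol(pairs)) stop("configuration error: no cross-group reference pairs")
  }
  pairs
}

#' Query-vs-reference triplet scan
#'
#' Scans only triplets (query, reference, reference), with the two
#' references drawn from different groups whenever more than one group is
#' defined; the query is the only admissible recombinant, so regions whose
#' pattern switch does not implicate the query are discarded. Consolidation
#' as in [scan_all()], restricted to same-query events.
#'
#' @param aln An [alignment()].
#' @param roles An [assign_roles()] result.
#' @param cfg A [scan_config()].
#' @return A `recomb_events` table with extra columns
#'   `major_parent_group`, `minor_parent_group`.
#' @export
query_scan <- function(aln, roles, cfg = scan_config()) {
  stopifnot(is_alignment(aln))
  if (!all(roles$name == aln$names)) {
    roles <- roles[match(aln$names, roles$name), , drop = FALSE]
    if (anyNA(roles$name)) stop("roles do not cover all alignment sequences")
  }
  queries <- which(roles$role == "query")
  if (!length(queries)) stop("configuration error: zero query sequences")
  pairs <- reference_pairs(roles)
  n_tri <- length(queries) * ncol(pairs)
  evs <- list()
  for (q in queries) {
    for (p in seq_len(ncol(pairs))) {
      prof <- build_triplet_profile(aln, q, pairs[1L, p], pairs[2L, p])
      regions <- suppressWarnings(scan_triplet(prof, cfg, n_triplets = n_tri))
      for (r in seq_len(nrow(regions))) {
        ev <- region_to_event(regions[r, ], prof, aln, cfg)
        if (ev$recombinant != aln$names[q]) next
        ev$major_parent_group <- roles$group[match(ev$major_parent, roles$name)]
        ev$minor_parent_group <- roles$group[match(ev$minor_parent, roles$name)]
        evs[[length(evs) + 1L]] <- ev
      }
    }
  }
  out <- event_table(evs)
  if (!nrow(out)) {
    out$major_parent_group <- character()
    out$minor_parent_group <- character()
  }
  consolidate_events(out)
}
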