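# Alignment and annotation file I/O. FASTA goes through Biostrings, NEXUS
# through ape, GFF3 through rtracklayer; the relaxed-name PHYLIP dialect
# (full name + single space, sequential or interleaved) and the GenBank
# FEATURES table are parsed here.

#' Read a nucleotide alignment
#'
#' Supported formats: FASTA, PHYLIP (sequential or interleaved, relaxed
#' names: full name followed by whitespace), and NEXUS DATA blocks. With
#' `format = "auto"` the first non-blank line decides: `>` means FASTA, a
#' leading digit PHYLIP, `#NEXUS` NEXUS.
#'
#' @param path File path.
#' @param format One of `"fasta"`, `"phylip"`, `"nexus"`, `"auto"`.
#' @return An [alignment()] (normalized uppercase, `U` mapped to `T`).
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "phylip", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    lines <- readLines(path, warn = FALSE)
    first <- lines[nzchar(trimws(lines))][1L]
    if (is.na(first)) stop("empty file: ", path)
    format <- if (startsWith(first, ">")) "fasta"
      else if (grepl("^\\s*[0-9]", first)) "phylip"
      else if (grepl("^#NEXUS", first, ignore.case = TRUE)) "nexus"
      else stop("cannot auto-detect alignment format of ", path)
  }
  switch(format,
    fasta = {
      ss <- Biostrings::readBStringSet(path)
      alignment(names(ss), as.character(ss))
    },
    phylip = read_phylip(path),
    nexus = {
      dat <- ape::read.nexus.data(path)
      alignment(names(dat), vapply(dat, paste, "", collapse = ""))
    })
}

read_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(hdr) < 2L) stop("malformed PHYLIP header in ", path)
  n <- as.integer(hdr[1L]); L <- as.integer(hdr[2L])
  body <- lines[-1L]
  if (length(body) < n) stop("PHYLIP file has fewer lines than sequences")
  parse_named <- function(line) {
    parts <- strsplit(trimws(line), "\\s+")[[1L]]
    list(name = parts[1L], chunk = paste(parts[-1L], collapse = ""))
  }
  # interleaved attempt: names in the first block only
  first <- lapply(body[seq_len(n)], parse_named)
  nms <- vapply(first, `[[`, "", "name")
  seqs <- vapply(first, `[[`, "", "chunk")
  rest <- body[-seq_len(n)]
  k <- 1L
  for (ln in rest) {
    seqs[k] <- paste0(seqs[k], gsub("\\s+", "", ln))
    k <- if (k == n) 1L else k + 1L
  }
  if (all(nchar(seqs) == L)) return(alignment(nms, seqs))
  # sequential fallback: each sequence is a name line plus continuations
  nms <- character(n); seqs <- character(n); i <- 1L
  for (s in seq_len(n)) {
    if (i > length(body)) stop("PHYLIP parse error: ran out of lines")
    p <- parse_named(body[i]); i <- i + 1L
    nms[s] <- p$name; seqs[s] <- p$chunk
    while (nchar(seqs[s]) < L) {
      if (i > length(body)) stop("PHYLIP sequence '", nms[s], "' shorter than ", L)
      seqs[s] <- paste0(seqs[s], gsub("\\s+", "", body[i])); i <- i + 1L
    }
    if (nchar(seqs[s]) != L) {
      stop("PHYLIP sequence '", nms[s], "' has length ", nchar(seqs[s]),
           ", expected ", L)
    }
  }
  alignment(nms, seqs)
}

#' Write an alignment to file
#'
#' FASTA records are written unwrapped in input order; PHYLIP uses relaxed
#' names (full identifier + single space, sequential); NEXUS writes a
#' standard DATA block re-readable by [read_alignment()].
#'
#' @param aln An [alignment()].
#' @param path Output path.
#' @param format One of `"fasta"`, `"phylip"`, `"nexus"`.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip", "nexus")) {
  format <- match.arg(format)
  if (!is_alignment(aln) || n_seq(aln) == 0L) {
    stop("refusing to write an empty alignment")
  }
  switch(format,
    fasta = {
      ss <- Biostrings::BStringSet(aln_strings(aln))
      Biostrings::writeXStringSet(ss, path, width = 100000L)
    },
    phylip = {
      con <- file(path, "w"); on.exit(close(con))
      writeLines(paste(n_seq(aln), aln_length(aln)), con)
      writeLines(paste(aln$names, aln_strings(aln)), con)
    },
    nexus = {
      dat <- lapply(aln$names, function(nm) aln$mat[nm, ])
      names(dat) <- aln$names
      ape::write.nexus.data(dat, path, format = "dna", interleaved = FALSE)
    })
  invisible(NULL)
}

#' Read a genome annotation into an annotation track
#'
#' Reads gene/CDS features from GFF3 or a GenBank flat-file FEATURES table.
#' File coordinates are 1-based inclusive; the returned track is 0-based
#' half-open, with multi-interval CDS (joins) kept in transcription order
#' (ascending for `+` strand, descending for `-`).
#'
#' @param path File path.
#' @param format `"gff3"`, `"genbank"`, or `"auto"` (sniffed from content).
#' @param aln_len Optional alignment length; coordinates beyond it raise an
#'   error.
#' @return An `annotation_track`: data frame with columns `feature_id`,
#'   `type` (gene/CDS), `start`, `end` (0-based half-open), `strand`,
#'   `phase`; one row per interval, interval rows of a feature adjacent and
#'   in transcription order.
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "genbank"),
                            aln_len = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 5L, warn = FALSE)
    format <- if (any(grepl("^##gff-version", first))) "gff3"
      else if (any(grepl("^(LOCUS|FEATURES)", first))) "genbank"
      else "gff3"
  }
  df <- if (format == "gff3") read_gff3_track(path) else read_genbank_track(path)
  validate_track(df, aln_len)
}

read_gff3_track <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% c("gene", "CDS")]
  if (length(gr) == 0L) return(empty_track())
  mc <- S4Vectors::mcols(gr)
  ids <- as.character(mc$ID)
  if ("Parent" %in% names(mc)) {
    parent <- vapply(mc$Parent, function(p)
      if (length(p)) as.character(p[1L]) else NA_character_, "")
  } else parent <- rep(NA_character_, length(gr))
  type <- as.character(mc$type)
  fid <- ifelse(type == "CDS" & !is.na(parent), parent,
                ifelse(!is.na(ids), ids, paste0("feature", seq_along(gr))))
  phase <- if ("phase" %in% names(mc)) as.integer(mc$phase) else rep(NA_integer_, length(gr))
  strand <- as.character(BiocGenerics::strand(gr))
  strand[!strand %in% c("+", "-")] <- "+"
  df <- data.frame(feature_id = fid, type = type,
                   start = BiocGenerics::start(gr) - 1L,
                   end = BiocGenerics::end(gr),
                   strand = strand,
                   phase = ifelse(is.na(phase), 0L, phase),
                   stringsAsFactors = FALSE)
  order_track(df)
}

# GenBank flat file, FEATURES section only: gene and CDS keys with
# location strings (a..b, join(...), complement(...), nested combinations).
read_genbank_track <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fstart <- grep("^FEATURES", lines)
  if (length(fstart)) lines <- lines[(fstart[1L] + 1L):length(lines)]
  stop_at <- grep("^(ORIGIN|CONTIG|//)", lines)
  if (length(stop_at)) lines <- lines[seq_len(stop_at[1L] - 1L)]
  recs <- list(); cur <- NULL
  for (ln in lines) {
    if (grepl("^ {5}\\S", ln)) {           # new feature key
      if (!is.null(cur)) recs[[length(recs) + 1L]] <- cur
      parts <- strsplit(trimws(ln), "\\s+")[[1L]]
      cur <- list(key = parts[1L], loc = paste(parts[-1L], collapse = ""),
                  quals = character())
    } else if (!is.null(cur)) {
      tx <- trimws(ln)
      if (startsWith(tx, "/")) cur$quals <- c(cur$quals, tx)
      else if (!grepl('"', tx) && grepl("^[0-9.,()<>a-z]+$", tx)) {
        cur$loc <- paste0(cur$loc, tx)   # wrapped location continuation
      }
    }
  }
  if (!is.null(cur)) recs[[length(recs) + 1L]] <- cur
  recs <- Filter(function(r) r$key %in% c("gene", "CDS"), recs)
  if (!length(recs)) return(empty_track())
  rows <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    loc <- parse_gb_location(r$loc)
    gq <- grep('^/(gene|locus_tag)=', r$quals, value = TRUE)
    fid <- if (length(gq)) gsub('^/[a-z_]+="?([^"]*)"?$', "\\1", gq[1L])
           else paste0(tolower(r$key), i)
    cq <- grep("^/codon_start=", r$quals, value = TRUE)
    phase0 <- if (length(cq)) as.integer(sub("^/codon_start=", "", cq[1L])) - 1L else 0L
    iv <- loc$intervals
    if (loc$strand == "-") iv <- iv[rev(seq_len(nrow(iv))), , drop = FALSE]
    data.frame(feature_id = fid, type = r$key,
               start = iv[, 1L] - 1L, end = iv[, 2L],
               strand = loc$strand,
               phase = c(phase0, rep(0L, nrow(iv) - 1L)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

parse_gb_location <- function(loc) {
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  iv <- t(vapply(parts, function(p) {
    p <- gsub("complement\\(|\\)", "", p)
    if (grepl("\\.\\.", p)) as.integer(strsplit(p, "\\.\\.")[[1L]][1:2])
    else rep(as.integer(p), 2L)
  }, integer(2L)))
  if (any(is.na(iv))) stop("unparseable GenBank location: ", loc)
  list(intervals = iv, strand = strand)
}

empty_track <- function() {
  structure(data.frame(feature_id = character(), type = character(),
                       start = integer(), end = integer(),
                       strand = character(), phase = integer(),
                       stringsAsFactors = FALSE),
            class = c("annotation_track", "data.frame"))
}

order_track <- function(df) {
  # transcription order within feature: ascending starts on '+', descending on '-'
  sp <- split(seq_len(nrow(df)), paste(df$feature_id, df$type))
  idx <- unlist(lapply(sp, function(ix) {
    ix[order(df$start[ix], decreasing = df$strand[ix[1L]] == "-")]
  }), use.names = FALSE)
  df[idx, , drop = FALSE]
}

validate_track <- function(df, aln_len = NULL) {
  if (nrow(df)) {
    if (any(!df$strand %in% c("+", "-"))) {
      stop("unknown strand symbol: ", unique(df$strand[!df$strand %in% c("+", "-")])[1L])
    }
    if (any(df$start < 0L | df$end <= df$start)) stop("invalid feature interval")
    if (!is.null(aln_len) && any(df$end > aln_len)) {
      stop("feature interval extends beyond alignment length ", aln_len)
    }
  }
  rownames(df) <- NULL
  class(df) <- c("annotation_track", "data.frame")
  df
}

#' Build an annotation track from a data frame
#'
#' Convenience constructor for programmatic annotation (0-based half-open
#' coordinates, same columns as [read_annotation()] returns).
#' @param df Data frame with columns `feature_id`, `type`, `start`, `end`,
#'   `strand`, and optionally `phase`.
#' @param aln_len Optional alignment length for coordinate validation.
#' @export
annotation_track <- function(df, aln_len = NULL) {
  if (is.null(df$phase)) df$phase <- rep(0L, nrow(df))
  validate_track(order_track(as.data.frame(df)), aln_len)
}
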