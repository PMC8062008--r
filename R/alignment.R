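# Core alignment container: a character matrix (rows = sequences, columns =
# alignment sites) stored uppercase over {A,C,G,T, IUPAC ambiguity, N, -}.

ALN_BASES <- c("A", "C", "G", "T")
ALN_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
ALN_CHARS <- c(ALN_BASES, ALN_AMBIG, "-")

#' Construct an alignment from sequence strings
#'
#' An `alignment` is the universal substrate of the package: named,
#' equal-length nucleotide rows. Input is normalized to uppercase, `U` is
#' mapped to `T` and `?` to `N`; anything outside the nucleotide / IUPAC
#' ambiguity / gap set is rejected with the offending column reported.
#'
#' @param names Character vector of unique sequence identifiers.
#' @param seqs Character vector of equal-length sequence strings (one per
#'   name), or a character matrix of single characters with one row per
#'   sequence.
#' @return An object of class `alignment`: a list with elements `names`
#'   (identifiers, in input order) and `mat` (character matrix, rows in the
#'   same order).
#' @examples
#' aln <- alignment(c("s1", "s2"), c("ACGT", "acgu"))
#' aln_length(aln) # 4
#' @export
alignment <- function(names, seqs) {
  names <- as.character(names)
  if (anyDuplicated(names)) {
    stop("duplicate sequence identifiers: ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    seqs <- as.character(seqs)
    if (length(seqs) != length(names)) {
      stop("'names' and 'seqs' lengths differ")
    }
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      bad <- names[lens != lens[1L]][1L]
      stop("ragged alignment: sequence '", bad, "' has length ",
           nchar(seqs[names == bad][1L]), ", expected ", lens[1L])
    }
    mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  }
  if (length(names) == 0L || ncol(mat) < 1L) {
    stop("alignment must contain at least one sequence of length >= 1")
  }
  mat <- toupper(mat)
  mat[mat == "U"] <- "T"
  mat[mat == "?"] <- "N"
  bad <- !(mat %in% ALN_CHARS)
  dim(bad) <- dim(mat)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("invalid character '", mat[bad][1L], "' in sequence '",
         names[idx[1L]], "' at column ", idx[2L])
  }
  rownames(mat) <- names
  structure(list(names = names, mat = mat), class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat("alignment: ", n_seq(x), " sequences x ", aln_length(x), " columns\n",
      sep = "")
  show <- utils::head(x$names, 5L)
  for (nm in show) {
    s <- paste(x$mat[nm, seq_len(min(50L, aln_length(x)))], collapse = "")
    cat(sprintf("  %-12s %s%s\n", nm, s,
                if (aln_length(x) > 50L) "..." else ""))
  }
  if (n_seq(x) > 5L) cat("  ... ", n_seq(x) - 5L, " more\n", sep = "")
  invisible(x)
}

#' Alignment dimensions
#' @param aln An `alignment`.
#' @return `aln_length`: number of columns; `n_seq`: number of sequences.
#' @export
aln_length <- function(aln) ncol(aln$mat)

#' @rdname aln_length
#' @export
n_seq <- function(aln) nrow(aln$mat)

#' Extract rows back into strings
#' @param aln An `alignment`.
#' @return Named character vector of sequence strings.
#' @export
aln_strings <- function(aln) {
  stats::setNames(apply(aln$mat, 1L, paste, collapse = ""), aln$names)
}

# Subset rows (by index or name) and/or columns; returns an alignment.
aln_subset <- function(aln, rows = NULL, cols = NULL) {
  if (is.null(rows)) rows <- seq_len(n_seq(aln))
  if (is.character(rows)) rows <- match(rows, aln$names)
  if (anyNA(rows)) stop("unknown sequence name in subset")
  if (is.null(cols)) cols <- seq_len(aln_length(aln))
  m <- aln$mat[rows, cols, drop = FALSE]
  structure(list(names = aln$names[rows], mat = m), class = "alignment")
}

is_alignment <- function(x) inherits(x, "alignment")

# TRUE where character is an unambiguous base; preserves dim.
is_base <- function(m) {
  out <- m %in% ALN_BASES
  dim(out) <- dim(m)
  out
}

#' Classify alignment columns
#'
#' Labels each column as `invariant`, `biallelic_informative` (two states,
#' each carried by at least two sequences), `biallelic_singleton`,
#' `multiallelic`, or `gapped_excluded` when the gap/ambiguity fraction
#' exceeds `max_missing_frac`. Gaps and IUPAC ambiguity codes count as
#' missing data throughout.
#'
#' @param aln An `alignment`.
#' @param max_missing_frac Maximum tolerated per-column missing fraction
#'   before the column is excluded (default 0.2).
#' @return Data frame with one row per column: `class` (factor) and
#'   `minor_count` (count of the rarest non-missing state; 0 for invariant
#'   or excluded columns).
#' @export
classify_sites <- function(aln, max_missing_frac = 0.2) {
  stopifnot(is_alignment(aln))
  m <- aln$mat
  n <- nrow(m)
  lv <- c("invariant", "biallelic_informative", "biallelic_singleton",
          "multiallelic", "gapped_excluded")
  out <- data.frame(class = factor(rep("invariant", ncol(m)), levels = lv),
                    minor_count = integer(ncol(m)))
  base <- is_base(m)
  miss_frac <- 1 - colSums(base) / n
  for (j in seq_len(ncol(m))) {
    if (miss_frac[j] > max_missing_frac) {
      out$class[j] <- "gapped_excluded"
      next
    }
    tab <- tabulate(match(m[base[, j], j], ALN_BASES), nbins = 4L)
    tab <- tab[tab > 0L]
    k <- length(tab)
    if (k <= 1L) {
      out$class[j] <- "invariant"
    } else if (k == 2L) {
      out$minor_count[j] <- min(tab)
      out$class[j] <- if (min(tab) >= 2L) "biallelic_informative"
                      else "biallelic_singleton"
    } else {
      out$minor_count[j] <- min(tab)
      out$class[j] <- "multiallelic"
    }
  }
  out
}

#' Pairwise identity over a window
#'
#' Fraction of identical positions between two rows over a half-open
#' 0-based column window. Columns where either row is gapped or ambiguous
#' are excluded from numerator and denominator.
#'
#' @param aln An `alignment`.
#' @param i,j Row indices (1-based) or sequence names; must differ.
#' @param window Integer pair `(start, end)`, 0-based half-open; defaults to
#'   the full alignment.
#' @return Fraction in `[0, 1]`, or `NA` when no comparable columns exist.
#' @export
pairwise_identity <- function(aln, i, j, window = c(0L, aln_length(aln))) {
  stopifnot(is_alignment(aln))
  if (is.character(i)) i <- match(i, aln$names)
  if (is.character(j)) j <- match(j, aln$names)
  if (is.na(i) || is.na(j)) stop("unknown sequence name")
  if (i == j) stop("self-comparison: i and j must differ")
  start <- window[1L]; end <- window[2L]
  if (!(start >= 0 && start < end && end <= aln_length(aln))) {
    stop("window must satisfy 0 <= start < end <= alignment length")
  }
  cols <- (start + 1L):end
  a <- aln$mat[i, cols]; b <- aln$mat[j, cols]
  ok <- is_base(a) & is_base(b)
  if (!any(ok)) return(NA_real_)
  sum(a[ok] == b[ok]) / sum(ok)
}

# Proportion of differing comparable sites (p-distance) between two rows.
p_distance <- function(aln, i, j) {
  id <- pairwise_identity(aln, i, j)
  if (is.na(id)) NA_real_ else 1 - id
}
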