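#' Read / write a protein multiple sequence alignment
#'
#' Thin wrappers over `Biostrings` FASTA I/O. On read, `.` gap characters
#' are normalised to `-` and equal sequence lengths are enforced.
#'
#' @param path Aligned FASTA file.
#' @return An `AAStringSet` with unique names and equal widths.
#' @export
read_msa <- function(path) {
  msa <- Biostrings::readAAStringSet(path)
  msa <- Biostrings::AAStringSet(chartr(".", "-", as.character(msa)))
  validate_msa(msa)
  msa
}

#' @rdname read_msa
#' @param msa An `AAStringSet` (or named character vector of aligned
#'   sequences).
#' @export
write_msa <- function(msa, path) {
  msa <- as_msa(msa)
  Biostrings::writeXStringSet(msa, path)
  invisible(path)
}

as_msa <- function(msa) {
  if (is.character(msa)) msa <- Biostrings::AAStringSet(msa)
  validate_msa(msa)
  msa
}

validate_msa <- function(msa) {
  if (length(msa) == 0L) stop("empty alignment")
  if (length(unique(Biostrings::width(msa))) != 1L) {
    stop("alignment sequences differ in length")
  }
  if (is.null(names(msa)) || anyDuplicated(names(msa))) {
    stop("alignment sequences must have unique names")
  }
  invisible(msa)
}

# character matrix view of an alignment (rows = sequences)
msa_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(as.character(msa), ""))
  rownames(m) <- names(msa)
  m
}

#' Per-column and per-sequence gap fractions
#'
#' @param msa Alignment (`AAStringSet` or named character vector). Only
#'   `-` counts as a gap; ambiguity codes (X, B, Z) are residues.
#' @return `column_gap_fractions()`: numeric vector, one entry per column.
#'   `sequence_gap_fractions()`: named numeric vector, one entry per
#'   sequence.
#' @export
column_gap_fractions <- function(msa) {
  m <- msa_matrix(as_msa(msa))
  colMeans(m == "-")
}

#' @rdname column_gap_fractions
#' @export
sequence_gap_fractions <- function(msa) {
  m <- msa_matrix(as_msa(msa))
  rowMeans(m == "-")
}

#' Remove alignment columns with too many gaps
#'
#' Drops every column whose gap fraction is strictly greater than
#' `max_col_gap_frac` ("over X% gaps"); a column at exactly the threshold
#' survives. Column order and sequence order are preserved. The preset
#' thresholds used for ribosomal-marker and homologue alignments are 0.5
#' and 0.9.
#'
#' @param msa Alignment (`AAStringSet` or named character vector).
#' @param max_col_gap_frac Gap-fraction threshold in `[0, 1]`.
#' @return List with `msa` (trimmed `AAStringSet`) and `removed` (1-based
#'   indices of the removed columns in the input).
#' @export
trim_columns <- function(msa, max_col_gap_frac = 0.5) {
  stopifnot(max_col_gap_frac >= 0, max_col_gap_frac <= 1)
  msa <- as_msa(msa)
  m <- msa_matrix(msa)
  gap_frac <- colMeans(m == "-")
  removed <- which(gap_frac > max_col_gap_frac)
  kept <- m[, setdiff(seq_len(ncol(m)), removed), drop = FALSE]
  out <- Biostrings::AAStringSet(apply(kept, 1L, paste, collapse = ""))
  names(out) <- names(msa)
  list(msa = out, removed = as.integer(removed))
}

#' Remove alignment sequences with too many gaps
#'
#' Drops every sequence whose gap fraction (over the current columns) is
#' strictly greater than `max_seq_gap_frac`; a sequence at exactly the
#' threshold survives. Intended to run after [trim_columns()] ("sequences
#' containing over 60% gaps in the trimmed alignment").
#'
#' @param msa Alignment (`AAStringSet` or named character vector).
#' @param max_seq_gap_frac Gap-fraction threshold in `[0, 1]`.
#' @return List with `msa` (filtered `AAStringSet`) and `removed`
#'   (character vector of removed sequence ids). All sequences being
#'   removed is an error.
#' @export
filter_sequences <- function(msa, max_seq_gap_frac = 0.6) {
  stopifnot(max_seq_gap_frac >= 0, max_seq_gap_frac <= 1)
  msa <- as_msa(msa)
  gap_frac <- sequence_gap_fractions(msa)
  drop <- gap_frac > max_seq_gap_frac
  if (all(drop)) stop("all sequences exceed the gap threshold")
  list(msa = msa[!drop], removed = names(msa)[drop])
}

#' Concatenate per-marker alignments into a supermatrix
#'
#' Builds a concatenated alignment over a fixed marker list (e.g. a set of
#' 15 ribosomal proteins). Genomes present in fewer than `min_markers`
#' marker alignments are excluded (and reported); a genome's missing
#' markers are padded with gap columns of that marker's alignment length.
#'
#' @param marker_msas Named list of alignments, one per marker, each an
#'   `AAStringSet` (or named character vector) whose names are genome ids.
#' @param markers Ordered marker ids to concatenate; defaults to
#'   `names(marker_msas)`. A marker absent from every genome is an error.
#' @param min_markers Minimum number of markers a genome must have to be
#'   kept (default 5).
#' @return List of class `supermatrix` with `msa` (the concatenated
#'   `AAStringSet`), `partitions` (data frame `marker`, `start`, `end`,
#'   1-based inclusive column intervals), `marker_counts` (named integer
#'   vector over all input genomes) and `excluded` (genome ids dropped for
#'   having too few markers).
#' @export
concatenate_markers <- function(marker_msas, markers = names(marker_msas),
                                min_markers = 5L) {
  stopifnot(length(markers) >= 1L, min_markers >= 1L,
            min_markers <= length(markers))
  absent <- markers[!markers %in% names(marker_msas)]
  if (length(absent) > 0L) {
    stop("marker(s) absent from every genome: ",
         paste(absent, collapse = ", "))
  }
  msas <- lapply(marker_msas[markers], as_msa)
  lens <- vapply(msas, function(m) Biostrings::width(m)[1L], integer(1))
  genomes <- sort(unique(unlist(lapply(msas, names))))
  counts <- vapply(genomes, function(g) {
    sum(vapply(msas, function(m) g %in% names(m), logical(1)))
  }, integer(1))
  excluded <- genomes[counts < min_markers]
  kept <- genomes[counts >= min_markers]
  if (length(kept) == 0L) stop("no genome reaches min_markers = ", min_markers)
  rows <- vapply(kept, function(g) {
    paste(vapply(seq_along(markers), function(i) {
      m <- msas[[i]]
      if (g %in% names(m)) as.character(m[[g]]) else
        strrep("-", lens[[i]])
    }, character(1)), collapse = "")
  }, character(1))
  ends <- cumsum(lens)
  partitions <- data.frame(marker = markers,
                           start = c(1L, utils::head(ends, -1L) + 1L),
                           end = ends, stringsAsFactors = FALSE)
  structure(list(msa = Biostrings::AAStringSet(rows),
                 partitions = partitions,
                 marker_counts = counts,
                 excluded = excluded),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("Supermatrix:", length(x$msa), "genomes x",
      Biostrings::width(x$msa)[1L], "columns,",
      nrow(x$partitions), "markers;", length(x$excluded),
      "genome(s) excluded\n")
  invisible(x)
}

#' Write a RAxML-style partition file
#'
#' One line per marker: `PROT, <marker> = <start>-<end>`.
#'
#' @param supermatrix A `supermatrix` from [concatenate_markers()] (or its
#'   `partitions` data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partitions <- function(supermatrix, path) {
  p <- if (is.data.frame(supermatrix)) supermatrix else supermatrix$partitions
  writeLines(sprintf("PROT, %s = %d-%d", p$marker, p$start, p$end), path)
  invisible(path)
}
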