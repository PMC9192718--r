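#' Co-location analysis configuration
#'
#' @param window_bp Positive window size in bp. A category pair co-locates
#'   in a genome when two of its genes fit in a region strictly smaller than
#'   this (default 10000, i.e. "within less than 10 kb").
#' @param count_fusion_as_colocated Should a single fusion gene carrying two
#'   categories count as those categories co-locating? Default `TRUE`: a
#'   fused gene is maximal co-location.
#' @param measure How the distance between two genes is measured:
#'   `"region"` (default) uses the length of the minimal region containing
#'   both genes; `"gap"` uses the nearest-edge distance between them. The
#'   two differ by the lengths of the genes themselves; the region reading
#'   follows the "co-locate within a region of" phrasing.
#' @return List of class `colocation_config`.
#' @export
colocation_config <- function(window_bp = 10000, count_fusion_as_colocated = TRUE,
                              measure = c("region", "gap")) {
  stopifnot(is.numeric(window_bp), length(window_bp) == 1L, window_bp > 0)
  measure <- match.arg(measure)
  structure(list(window_bp = window_bp,
                 count_fusion_as_colocated = isTRUE(count_fusion_as_colocated),
                 measure = measure),
            class = "colocation_config")
}

#' Span of the minimal region containing two genes
#'
#' For two genes of the same genome on the same contig, the length in bp of
#' the smallest contiguous region covering both (1-based inclusive):
#' `max(end1, end2) - min(start1, start2) + 1`. Genes on different contigs
#' have no defined span (`NA`); genes from different genomes are an error.
#'
#' @param g1,g2 Single-row gene data frames (or lists) with `genome_id`,
#'   `contig_id`, `start`, `end`.
#' @return Span in bp, or `NA` if the genes lie on different contigs.
#' @export
#' @examples
#' g1 <- list(genome_id = "G", contig_id = "c1", start = 100, end = 1099)
#' g2 <- list(genome_id = "G", contig_id = "c1", start = 5000, end = 5999)
#' pair_span(g1, g2)  # 5900
pair_span <- function(g1, g2) {
  if (g1$genome_id != g2$genome_id) {
    stop("pair_span is undefined across genomes (",
         g1$genome_id, " vs ", g2$genome_id, ")")
  }
  if (g1$contig_id != g2$contig_id) return(NA_real_)
  max(g1$end, g2$end) - min(g1$start, g2$start) + 1
}

# vectorised distance between gene i and all genes in a catalogue block;
# measure "region": minimal containing region length; "gap": edge distance
# (0 for overlapping genes)
pair_measure_vec <- function(entries, i, cfg) {
  same <- entries$contig_id == entries$contig_id[i]
  if (cfg$measure == "region") {
    d <- pmax(entries$end, entries$end[i]) -
      pmin(entries$start, entries$start[i]) + 1
  } else {
    d <- pmax(entries$start, entries$start[i]) -
      pmin(entries$end, entries$end[i]) - 1
    d <- pmax(d, 0)
  }
  d[!same] <- NA_real_
  d
}

#' Does a category pair co-locate in one genome?
#'
#' Tri-state co-location call for a single genome: `"absent"` when either
#' category has no catalogued gene; `"colocated"` when two genes (or one
#' fusion gene, if configured) place the pair within the window;
#' `"coexisting_only"` otherwise. For `cat_a == cat_b` two distinct genes
#' are required -- a gene cannot co-locate with itself.
#'
#' @param entries Catalogue rows (see [build_catalogue()]) of one genome.
#' @param cat_a,cat_b Functional category labels.
#' @param cfg A [colocation_config()].
#' @return One of `"colocated"`, `"coexisting_only"`, `"absent"`.
#' @export
genome_colocates <- function(entries, cat_a, cat_b, cfg = colocation_config()) {
  if (nrow(entries) > 0L && length(unique(entries$genome_id)) > 1L) {
    stop("entries must belong to a single genome")
  }
  cats <- split_categories(entries$categories)
  has_a <- vapply(cats, function(x) cat_a %in% x, logical(1))
  has_b <- vapply(cats, function(x) cat_b %in% x, logical(1))
  if (!any(has_a) || !any(has_b)) return("absent")
  # a single fusion gene carrying both categories
  if (cat_a != cat_b && cfg$count_fusion_as_colocated) {
    both <- which(has_a & has_b)
    if (length(both) > 0L) {
      lens <- entries$end[both] - entries$start[both] + 1
      span_ok <- if (cfg$measure == "region") lens < cfg$window_bp else TRUE
      if (any(span_ok)) return("colocated")
    }
  }
  for (i in which(has_a)) {
    d <- pair_measure_vec(entries, i, cfg)
    j <- which(has_b)
    j <- j[j != i]
    if (any(!is.na(d[j]) & d[j] < cfg$window_bp)) return("colocated")
  }
  "coexisting_only"
}

#' Co-location fraction matrix over a genome set
#'
#' For every unordered pair of functional categories, counts across the
#' genomes of a set how often the pair coexists (both categories catalogued)
#' and how often it co-locates within the window, and reports the fraction
#' `n_colocated / n_coexisting`. Pairs never found coexisting get an `NA`
#' fraction -- deliberately distinct from an observed fraction of 0, so a
#' "never co-existing" cell can be rendered differently (white) from a
#' "co-existing but never clustered" cell.
#'
#' @param genome_ids Character vector: the genomes of the set. Genomes with
#'   no catalogued gene still count in the set (they simply lack every
#'   category).
#' @param catalogue Catalogue data frame covering (at least) those genomes.
#' @param cfg A [colocation_config()].
#' @param categories Ordered category labels for the matrix axes; defaults
#'   to [escrt_categories()].
#' @param set_id Label for the genome set (e.g. a phylum name).
#' @return List of class `colocation_matrix` with elements `set_id`,
#'   `categories`, and three symmetric matrices `fraction`, `n_colocated`,
#'   `n_coexisting`.
#' @export
colocation_matrix <- function(genome_ids, catalogue,
                              cfg = colocation_config(),
                              categories = escrt_categories(),
                              set_id = "set") {
  if (length(genome_ids) == 0L) stop("empty genome set")
  stopifnot(!anyDuplicated(genome_ids))
  k <- length(categories)
  n_col <- matrix(0L, k, k, dimnames = list(categories, categories))
  n_coex <- matrix(0L, k, k, dimnames = list(categories, categories))
  by_genome <- split(catalogue, factor(catalogue$genome_id, levels = genome_ids))
  for (g in genome_ids) {
    entries <- by_genome[[g]]
    if (is.null(entries) || nrow(entries) == 0L) next
    for (a in seq_len(k)) {
      for (b in a:k) {
        st <- genome_colocates(entries, categories[a], categories[b], cfg)
        if (st != "absent") {
          n_coex[a, b] <- n_coex[a, b] + 1L
          if (st == "colocated") n_col[a, b] <- n_col[a, b] + 1L
        }
      }
    }
  }
  n_col[lower.tri(n_col)] <- t(n_col)[lower.tri(n_col)]
  n_coex[lower.tri(n_coex)] <- t(n_coex)[lower.tri(n_coex)]
  frac <- ifelse(n_coex > 0L, n_col / n_coex, NA_real_)
  structure(list(set_id = set_id, categories = categories,
                 fraction = frac, n_colocated = n_col,
                 n_coexisting = n_coex),
            class = "colocation_matrix")
}

#' @export
print.colocation_matrix <- function(x, ...) {
  cat("Co-location matrix for set '", x$set_id, "' (",
      length(x$categories), " categories)\n", sep = "")
  cat("defined cells:", sum(!is.na(x$fraction[upper.tri(x$fraction, diag = TRUE)])),
      "of", sum(upper.tri(x$fraction, diag = TRUE)), "\n")
  print(round(x$fraction, 2))
  invisible(x)
}

#' Long-format export of a co-location matrix
#'
#' One row per unordered category pair: `set_id, cat_a, cat_b, fraction,
#' n_colocated, n_coexisting`. `NA` fractions (never-coexisting pairs) are
#' written as the literal string `NA`, distinct from `0`.
#'
#' @param m A `colocation_matrix`.
#' @param path Optional TSV output path.
#' @return Data frame (invisibly when `path` is given).
#' @export
colocation_long <- function(m, path = NULL) {
  k <- length(m$categories)
  idx <- which(upper.tri(m$fraction, diag = TRUE), arr.ind = TRUE)
  out <- data.frame(
    set_id = m$set_id,
    cat_a = m$categories[idx[, 1L]],
    cat_b = m$categories[idx[, 2L]],
    fraction = m$fraction[idx],
    n_colocated = m$n_colocated[idx],
    n_coexisting = m$n_coexisting[idx],
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    return(invisible(out))
  }
  out
}

#' Write the square fraction matrix as TSV
#'
#' @param m A `colocation_matrix`.
#' @param path Output TSV path; `NA` cells written as `NA`.
#' @return `path`, invisibly.
#' @export
write_colocation_matrix <- function(m, path) {
  utils::write.table(m$fraction, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA, na = "NA")
  invisible(path)
}

#' Heatmap of a co-location matrix
#'
#' Renders the fraction matrix with a white-to-dark gradient; `NA`
#' (never-coexisting) cells are drawn in white and are visually distinct
#' from defined 0 cells only through the displayed numbers. Requires the
#' `pheatmap` package.
#'
#' @param m A `colocation_matrix`.
#' @param filename Optional output file (png/pdf) passed to `pheatmap`.
#' @return The `pheatmap` object, invisibly.
#' @export
plot_colocation <- function(m, filename = NA) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop("plot_colocation requires the 'pheatmap' package")
  }
  p <- pheatmap::pheatmap(
    m$fraction, cluster_rows = FALSE, cluster_cols = FALSE,
    breaks = seq(0, 1, length.out = 101),
    color = grDevices::colorRampPalette(c("#f7f4f9", "#3f007d"))(100),
    na_col = "white", display_numbers = TRUE, number_format = "%.2f",
    main = paste0("Co-location fraction (", m$set_id, ")"),
    filename = filename, silent = !is.na(filename))
  invisible(p)
}
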