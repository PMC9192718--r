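#' Parse an InterProScan tab-separated annotation file
#'
#' Reads the 15-column InterProScan TSV dialect and returns one domain hit
#' per row that carries an InterPro accession. Rows whose InterPro column is
#' `"-"` (signature not integrated into InterPro) are skipped and counted.
#' Only the columns the downstream classification uses are retained: protein
#' accession (column 1), match coordinates (columns 7-8), score (column 9)
#' and InterPro accession (column 12).
#'
#' @param path Path to an InterProScan TSV file. An empty file yields an
#'   empty hit table (not an error).
#' @param min_cols Minimum number of tab-separated fields a row must have
#'   (InterProScan emits 11-15 depending on optional columns; the InterPro
#'   accession lives in column 12). Rows with fewer fields raise a parse
#'   error naming the line.
#' @return Data frame of domain hits with columns `protein_id`,
#'   `interpro_id`, `aa_start`, `aa_end`, `evalue`, and an attribute
#'   `n_skipped` giving the number of rows without an InterPro accession.
#' @export
parse_interproscan_tsv <- function(path, min_cols = 12L) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- data.frame(protein_id = character(), interpro_id = character(),
                      aa_start = integer(), aa_end = integer(),
                      evalue = numeric(), stringsAsFactors = FALSE)
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < min_cols)) {
    bad <- which(nf < min_cols)[1L]
    stop("malformed InterProScan row at line ", bad, ": expected at least ",
         min_cols, " tab-separated fields, found ", nf[bad])
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  ipr <- get(12L)
  keep <- ipr != "-" & ipr != ""
  bad_ipr <- keep & !grepl("^IPR[0-9]{6}$", ipr)
  if (any(bad_ipr)) {
    stop("malformed InterPro accession at line ", which(bad_ipr)[1L], ": ",
         ipr[which(bad_ipr)[1L]])
  }
  ev <- suppressWarnings(as.numeric(get(9L)))
  out <- data.frame(
    protein_id = get(1L)[keep],
    interpro_id = ipr[keep],
    aa_start = as.integer(get(7L)[keep]),
    aa_end = as.integer(get(8L)[keep]),
    evalue = ev[keep],
    stringsAsFactors = FALSE
  )
  if (any(stats::na.omit(out$aa_start > out$aa_end))) {
    stop("domain hit with aa_start > aa_end in ", path)
  }
  attr(out, "n_skipped") <- sum(!keep)
  out
}

#' Classify one protein's domain hits into functional categories
#'
#' Returns the union of diagnostic categories over all InterPro accessions
#' observed on a protein. Accessions absent from the diagnostic map
#' contribute nothing; a protein with no diagnostic hit yields an empty
#' character vector (a valid result, not an error). Duplicated hits do not
#' change the output.
#'
#' @param interpro_ids Character vector of InterPro accessions observed on
#'   one protein (e.g. the `interpro_id` column of the hits for that
#'   protein).
#' @param diagnostic_map Two-column data frame (`interpro_id`, `category`);
#'   defaults to [default_diagnostic_map()].
#' @param expand_composite If `TRUE`, the composite `Vps23/37/28` category is
#'   replaced by `Vps23/37` and `Vps28` in the result.
#' @return Character vector of categories (possibly empty), in the canonical
#'   order of [escrt_categories()].
#' @export
#' @examples
#' classify_protein(c("IPR017916", "IPR007143"))  # a Vps23/37-Vps28 fusion
classify_protein <- function(interpro_ids,
                             diagnostic_map = default_diagnostic_map(),
                             expand_composite = FALSE) {
  cats <- unique(diagnostic_map$category[
    diagnostic_map$interpro_id %in% interpro_ids])
  if (expand_composite && "Vps23/37/28" %in% cats) {
    cats <- unique(c(setdiff(cats, "Vps23/37/28"), "Vps23/37", "Vps28"))
  }
  order_ref <- unique(c(escrt_categories(), diagnostic_map$category))
  cats[order(match(cats, order_ref))]
}

#' Classify every protein in a domain-hit table
#'
#' @param hits Data frame as returned by [parse_interproscan_tsv()].
#' @inheritParams classify_protein
#' @return Named list mapping each protein_id with at least one diagnostic
#'   hit to its character vector of categories.
#' @export
classify_proteins <- function(hits,
                              diagnostic_map = default_diagnostic_map(),
                              expand_composite = FALSE) {
  by_prot <- split(hits$interpro_id, hits$protein_id)
  cl <- lapply(by_prot, classify_protein, diagnostic_map = diagnostic_map,
               expand_composite = expand_composite)
  cl[lengths(cl) > 0L]
}

#' Build the ubiquitin/ESCRT gene catalogue
#'
#' Joins classified proteins onto located genes: one catalogue entry per
#' gene whose protein carries at least one diagnostic category. Genes whose
#' protein has no (or an empty) classification are excluded. Classified
#' proteins with no matching gene are reported with a warning and skipped.
#'
#' @param genes Data frame of genes with columns `gene_id`, `genome_id`,
#'   `contig_id`, `start`, `end`, `strand`, `protein_id` (see
#'   [read_genes_gff3()]).
#' @param classifications Named list `protein_id -> character vector of
#'   categories`, as returned by [classify_proteins()].
#' @return Data frame with the gene columns plus `categories`
#'   (semicolon-joined) and `is_fusion` (`TRUE` when more than one category).
#' @export
build_catalogue <- function(genes, classifications) {
  validate_genes(genes)
  classifications <- classifications[lengths(classifications) > 0L]
  orphan <- setdiff(names(classifications), genes$protein_id)
  if (length(orphan) > 0L) {
    warning("classified protein(s) with no matching gene, skipped: ",
            paste(orphan, collapse = ", "))
  }
  keep <- genes$protein_id %in% names(classifications)
  cat_df <- genes[keep, , drop = FALSE]
  cats <- classifications[cat_df$protein_id]
  cat_df$categories <- vapply(cats, paste, character(1), collapse = ";")
  cat_df$is_fusion <- lengths(cats) > 1L
  rownames(cat_df) <- NULL
  cat_df
}

validate_genes <- function(genes) {
  need <- c("gene_id", "genome_id", "contig_id", "start", "end",
            "strand", "protein_id")
  stopifnot(is.data.frame(genes), all(need %in% names(genes)))
  if (nrow(genes) == 0L) return(invisible(genes))
  if (any(genes$start < 1L) || any(genes$start > genes$end)) {
    stop("gene coordinates must satisfy 1 <= start <= end (1-based inclusive)")
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'")
  }
  key <- paste(genes$genome_id, genes$gene_id)
  if (anyDuplicated(key)) {
    stop("duplicate (genome_id, gene_id): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  invisible(genes)
}

#' Split a semicolon-joined category field
#'
#' @param categories Character vector of `;`-joined category strings, as in
#'   the `categories` column of a catalogue.
#' @return List of character vectors.
#' @export
split_categories <- function(categories) {
  strsplit(categories, ";", fixed = TRUE)
}

#' Read genes from a GFF3 file
#'
#' Imports gene/CDS features via `rtracklayer` and returns the flat gene
#' table used throughout the package. Coordinates stay 1-based inclusive
#' (the GFF3 convention). Contig lengths are taken from the
#' `##sequence-region` pragma lines.
#'
#' @param path GFF3 file for one genome.
#' @param genome_id Genome identifier to stamp on every gene; defaults to
#'   the file name without extension.
#' @param feature_types GFF3 `type` values treated as genes (default
#'   `c("gene", "CDS")`; a feature's `ID` attribute is the gene_id and its
#'   `protein_id` attribute, when present, links it to a protein).
#' @return Data frame of genes (columns as in [build_catalogue()]), with a
#'   `contig_lengths` attribute: named numeric vector from the
#'   `##sequence-region` pragmas (may be empty if the file carries none).
#' @export
read_genes_gff3 <- function(path, genome_id = NULL,
                            feature_types = c("gene", "CDS")) {
  stopifnot(file.exists(path))
  if (is.null(genome_id)) {
    genome_id <- sub("\\.gff3?(\\.gz)?$", "", basename(path))
  }
  gr <- rtracklayer::import(path)
  gr <- gr[as.character(gr$type) %in% feature_types]
  meta <- S4Vectors::mcols(gr)
  gene_id <- if ("ID" %in% names(meta)) as.character(meta$ID) else
    paste0("gene", seq_along(gr))
  protein_id <- if ("protein_id" %in% names(meta)) {
    as.character(meta$protein_id)
  } else {
    gene_id
  }
  protein_id[is.na(protein_id)] <- gene_id[is.na(protein_id)]
  genes <- data.frame(
    gene_id = gene_id,
    genome_id = genome_id,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    protein_id = protein_id,
    stringsAsFactors = FALSE
  )
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  validate_genes(genes)
  attr(genes, "contig_lengths") <- read_sequence_regions(path)
  genes
}

#' Read contig lengths from GFF3 `##sequence-region` pragmas
#'
#' @param path GFF3 file.
#' @return Named numeric vector `contig_id -> length`.
#' @export
read_sequence_regions <- function(path) {
  lines <- grep("^##sequence-region", readLines(path), value = TRUE)
  if (length(lines) == 0L) return(stats::setNames(numeric(0), character(0)))
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  stats::setNames(
    vapply(parts, function(p) as.numeric(p[[4L]]), numeric(1)),
    vapply(parts, `[[`, character(1), 2L)
  )
}

#' Write / read a gene catalogue TSV
#'
#' @param catalogue Data frame from [build_catalogue()].
#' @param path Output TSV path.
#' @return `path` invisibly ([write_catalogue()]); catalogue data frame
#'   ([read_catalogue()]).
#' @export
write_catalogue <- function(catalogue, path) {
  cols <- c("genome_id", "contig_id", "gene_id", "start", "end", "strand",
            "protein_id", "categories", "is_fusion")
  utils::write.table(catalogue[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalogue
#' @export
read_catalogue <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
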