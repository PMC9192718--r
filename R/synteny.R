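#' Synteny analysis configuration
#'
#' @param flank_bp Non-negative flank in bp drawn on each side of a
#'   catalogued gene (default 2000: regions extend up to 2 kb from the
#'   ubiquitin/ESCRT genes, or until a contig boundary).
#' @param evalue_max Positive e-value ceiling for similarity hits; hits must
#'   be strictly below it (default 1e-5).
#' @return List of class `synteny_config`.
#' @export
synteny_config <- function(flank_bp = 2000, evalue_max = 1e-5) {
  stopifnot(is.numeric(flank_bp), flank_bp >= 0,
            is.numeric(evalue_max), evalue_max > 0)
  structure(list(flank_bp = flank_bp, evalue_max = evalue_max),
            class = "synteny_config")
}

#' Extract genome regions around catalogued genes
#'
#' For each catalogued gene, a window `[start - flank, end + flank]` is
#' drawn and clipped to the contig (`[1, contig_length]`). Overlapping or
#' abutting windows on the same contig are merged into one region. Region
#' members are all genes of the genome -- catalogued or not -- overlapping
#' the merged window; `clipped_left`/`clipped_right` record where a contig
#' boundary truncated the flank.
#'
#' @param genes All genes of one genome (data frame, see
#'   [read_genes_gff3()]).
#' @param catalogue Catalogue rows for the same genome; the regions are
#'   anchored on these genes.
#' @param contig_lengths Named numeric vector `contig_id -> length`. Every
#'   contig carrying a catalogued gene must be present.
#' @param cfg A [synteny_config()].
#' @return List with `regions` (data frame: `region_id`, `genome_id`,
#'   `contig_id`, `start`, `end`, `contig_length`, `clipped_left`,
#'   `clipped_right`, `n_members`) and `members` (data frame: `region_id`
#'   plus the gene columns and `is_catalogued`).
#' @export
extract_regions <- function(genes, catalogue, contig_lengths,
                            cfg = synteny_config()) {
  stopifnot(nrow(catalogue) > 0L)
  genome <- unique(catalogue$genome_id)
  stopifnot(length(genome) == 1L)
  missing_ctg <- setdiff(unique(catalogue$contig_id), names(contig_lengths))
  if (length(missing_ctg) > 0L) {
    stop("unknown contig length for contig(s): ",
         paste(missing_ctg, collapse = ", "))
  }
  regions <- NULL
  for (ctg in sort(unique(catalogue$contig_id))) {
    len <- contig_lengths[[ctg]]
    anchors <- catalogue[catalogue$contig_id == ctg, , drop = FALSE]
    ws <- anchors$start - cfg$flank_bp       # desired (pre-clip) starts
    we <- anchors$end + cfg$flank_bp
    o <- order(ws, we)
    ws <- ws[o]; we <- we[o]
    # merge overlapping or abutting (distance-0) windows in desired space
    m_start <- ws[1L]; m_end <- we[1L]
    merged <- list()
    if (length(ws) > 1L) {
      for (i in 2L:length(ws)) {
        if (ws[i] <= m_end + 1) {
          m_end <- max(m_end, we[i])
        } else {
          merged[[length(merged) + 1L]] <- c(m_start, m_end)
          m_start <- ws[i]; m_end <- we[i]
        }
      }
    }
    merged[[length(merged) + 1L]] <- c(m_start, m_end)
    for (w in merged) {
      regions <- rbind(regions, data.frame(
        genome_id = genome, contig_id = ctg,
        start = max(1, w[1L]), end = min(len, w[2L]),
        contig_length = len,
        clipped_left = w[1L] < 1, clipped_right = w[2L] > len,
        stringsAsFactors = FALSE))
    }
  }
  regions <- regions[order(regions$contig_id, regions$start), , drop = FALSE]
  regions$region_id <- sprintf("%s:%s:%d-%d", regions$genome_id,
                               regions$contig_id, regions$start, regions$end)
  members <- NULL
  cat_key <- paste(catalogue$genome_id, catalogue$gene_id)
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    hit <- genes$genome_id == r$genome_id & genes$contig_id == r$contig_id &
      genes$start <= r$end & genes$end >= r$start
    mem <- genes[hit, , drop = FALSE]
    if (nrow(mem) > 0L) {
      mem$region_id <- r$region_id
      mem$is_catalogued <- paste(mem$genome_id, mem$gene_id) %in% cat_key
      members <- rbind(members, mem)
    }
  }
  regions$n_members <- as.integer(table(factor(members$region_id,
                                               levels = regions$region_id)))
  rownames(regions) <- NULL
  if (!is.null(members)) rownames(members) <- NULL
  cols <- c("region_id", "genome_id", "contig_id", "start", "end",
            "contig_length", "clipped_left", "clipped_right", "n_members")
  list(regions = regions[, cols], members = members)
}

#' Read BLAST tabular output (12-column `-outfmt 6`)
#'
#' @param path BLAST tabular file (`qseqid sseqid pident length mismatch
#'   gapopen qstart qend sstart send evalue bitscore`).
#' @return Data frame with columns `query_id`, `subject_id`, `evalue`,
#'   `bitscore` (plus the remaining standard columns).
#' @export
read_blast_tabular <- function(path) {
  cols <- c("query_id", "subject_id", "pident", "length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue",
            "bitscore")
  hits <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(hits) != 12L) {
    stop("expected 12-column BLAST tabular output, found ", ncol(hits),
         " columns in ", path)
  }
  names(hits) <- cols
  hits
}

# best subject per query: highest bitscore, then lowest evalue, then
# lexicographically smallest subject_id -- fully deterministic
best_hit_per_query <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  o <- order(hits$query_id, -hits$bitscore, hits$evalue, hits$subject_id)
  hits <- hits[o, , drop = FALSE]
  hits[!duplicated(hits$query_id), , drop = FALSE]
}

#' Reciprocal best hits between two genomes
#'
#' Filters both direction tables to hits with e-value strictly below
#' `cfg$evalue_max`, keeps each query's single best subject (by bitscore,
#' ties broken by lower e-value then lexicographically smaller subject id),
#' and emits the pairs that are mutual bests.
#'
#' @param hits_ab,hits_ba Data frames of similarity hits with columns
#'   `query_id`, `subject_id`, `bitscore`, `evalue` (e.g. from
#'   [read_blast_tabular()] or [similarity_search()]); `hits_ab` queries
#'   genome A proteins against genome B, `hits_ba` the reverse.
#' @param cfg A [synteny_config()].
#' @return Data frame with columns `protein_a`, `protein_b`, `bitscore_ab`,
#'   `bitscore_ba`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, cfg = synteny_config()) {
  empty <- data.frame(protein_a = character(), protein_b = character(),
                      bitscore_ab = numeric(), bitscore_ba = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(hits_ab) == 0L || nrow(hits_ba) == 0L) return(empty)
  hits_ab <- hits_ab[hits_ab$evalue < cfg$evalue_max, , drop = FALSE]
  hits_ba <- hits_ba[hits_ba$evalue < cfg$evalue_max, , drop = FALSE]
  best_ab <- best_hit_per_query(hits_ab)
  best_ba <- best_hit_per_query(hits_ba)
  if (nrow(best_ab) == 0L || nrow(best_ba) == 0L) return(empty)
  back <- stats::setNames(best_ba$subject_id, best_ba$query_id)
  mutual <- !is.na(back[best_ab$subject_id]) &
    back[best_ab$subject_id] == best_ab$query_id
  mutual[is.na(mutual)] <- FALSE
  out <- data.frame(
    protein_a = best_ab$query_id[mutual],
    protein_b = best_ab$subject_id[mutual],
    bitscore_ab = best_ab$bitscore[mutual],
    stringsAsFactors = FALSE
  )
  out$bitscore_ba <- best_ba$bitscore[match(out$protein_b, best_ba$query_id)]
  out <- out[order(out$protein_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Karlin-Altschul constants for gapped BLOSUM62 with gap open 11 / extend 1,
# as used by protein BLAST. Approximate by construction; external BLAST
# tabular input is the fidelity path.
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Score one protein pair by Smith-Waterman local alignment
#'
#' Local alignment under BLOSUM62 with affine gap costs (open 11, extend 1),
#' computed with `Biostrings::pairwiseAlignment`. The raw score is converted
#' to a bit score with the standard gapped Karlin-Altschul constants
#' (lambda = 0.267, K = 0.041) and to an e-value as
#' `m * n * 2^(-bitscore)` for sequence lengths `m`, `n`. This built-in
#' scorer lets synthetic datasets be linked without an external BLAST
#' installation; its statistics are approximate.
#'
#' @param seq_a,seq_b Amino-acid sequences (single strings over the 20
#'   canonical letters). Empty sequences score 0.
#' @return One-row data frame: `query_id` (`NA`), `subject_id` (`NA`),
#'   `score`, `bitscore`, `evalue`.
#' @export
pairwise_similarity <- function(seq_a, seq_b) {
  check_aa(seq_a); check_aa(seq_b)
  if (nchar(seq_a) == 0L || nchar(seq_b) == 0L) {
    raw <- 0
  } else {
    raw <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
      type = "local", substitutionMatrix = blosum62(),
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
  }
  bits <- (KA_LAMBDA * raw - log(KA_K)) / log(2)
  ev <- nchar(seq_a) * nchar(seq_b) * 2^(-bits)
  data.frame(query_id = NA_character_, subject_id = NA_character_,
             score = raw, bitscore = bits, evalue = ev,
             stringsAsFactors = FALSE)
}

#' All-vs-all similarity search between two protein sets
#'
#' Applies [pairwise_similarity()] to every query/subject combination,
#' returning a hit table in the shape [reciprocal_best_hits()] consumes.
#'
#' @param queries,subjects Named character vectors of amino-acid sequences.
#' @return Data frame with columns `query_id`, `subject_id`, `score`,
#'   `bitscore`, `evalue`.
#' @export
similarity_search <- function(queries, subjects) {
  stopifnot(length(names(queries)) == length(queries),
            length(names(subjects)) == length(subjects))
  grid <- expand.grid(q = names(queries), s = names(subjects),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    h <- pairwise_similarity(queries[[grid$q[i]]], subjects[[grid$s[i]]])
    h$query_id <- grid$q[i]
    h$subject_id <- grid$s[i]
    h
  })
  do.call(rbind, rows)
}

check_aa <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  bad <- regmatches(seq, regexpr("[^ACDEFGHIKLMNPQRSTVWY]", seq))
  if (length(bad) > 0L && nzchar(bad)) {
    stop("non-canonical amino-acid character '", bad, "' in sequence")
  }
  invisible(seq)
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Link synteny regions of two genomes through reciprocal best hits
#'
#' One link per RBH pair whose two proteins both lie within an extracted
#' region of their respective genome. Pairs with either protein outside all
#' regions are dropped; the count of dropped pairs is attached as the
#' `n_dropped` attribute.
#'
#' @param regions_a,regions_b Outputs of [extract_regions()] for the two
#'   genomes.
#' @param rbh Data frame from [reciprocal_best_hits()] with genome-A
#'   proteins in `protein_a`.
#' @return Data frame with columns `region_a`, `gene_a`, `protein_a`,
#'   `region_b`, `gene_b`, `protein_b`; attribute `n_dropped`.
#' @export
synteny_links <- function(regions_a, regions_b, rbh) {
  find_member <- function(members, protein) {
    i <- which(members$protein_id == protein)
    if (length(i) == 0L) NULL else members[i[1L], ]
  }
  out <- data.frame(region_a = character(), gene_a = character(),
                    protein_a = character(), region_b = character(),
                    gene_b = character(), protein_b = character(),
                    stringsAsFactors = FALSE)
  dropped <- 0L
  for (i in seq_len(nrow(rbh))) {
    ma <- find_member(regions_a$members, rbh$protein_a[i])
    mb <- find_member(regions_b$members, rbh$protein_b[i])
    if (is.null(ma) || is.null(mb)) {
      dropped <- dropped + 1L
      next
    }
    out <- rbind(out, data.frame(
      region_a = ma$region_id, gene_a = ma$gene_id,
      protein_a = rbh$protein_a[i],
      region_b = mb$region_id, gene_b = mb$gene_id,
      protein_b = rbh$protein_b[i], stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  out
}

#' Export regions as BED
#'
#' Converts the internal 1-based inclusive region coordinates to the BED
#' convention (0-based half-open).
#'
#' @param regions Region data frame from [extract_regions()].
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
regions_to_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$contig_id,
                    chromStart = regions$start - 1L,
                    chromEnd = regions$end,
                    name = regions$region_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
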