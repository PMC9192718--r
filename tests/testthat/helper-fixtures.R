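# Shared fixture builders and independent brute-force oracles.

make_gene <- function(gene_id, start, end, genome_id = "G1",
                      contig_id = "c1", strand = "+",
                      protein_id = paste0(gene_id, "_p")) {
  data.frame(gene_id = gene_id, genome_id = genome_id, contig_id = contig_id,
             start = start, end = end, strand = strand,
             protein_id = protein_id, stringsAsFactors = FALSE)
}

make_entry <- function(gene_id, start, end, categories, genome_id = "G1",
                       contig_id = "c1") {
  g <- make_gene(gene_id, start, end, genome_id, contig_id)
  g$categories <- paste(categories, collapse = ";")
  g$is_fusion <- length(categories) > 1L
  g
}

# Write a minimal InterProScan 15-column TSV row.
ipr_row <- function(protein, ipr, start = 1L, end = 100L, score = "1e-30") {
  paste(protein, "md5", "200", "Pfam", "PF00000", "desc", start, end,
        score, "T", "2020-12-05", ipr, "entry", "-", "-", sep = "\t")
}

# Independent brute-force co-location oracle: plain double loop over the
# catalogue rows of each genome, recomputing spans from scratch. Kept free
# of any package internals beyond the data-frame layout.
naive_colocation_matrix <- function(genome_ids, catalogue, window_bp = 10000,
                                    categories = escrt_categories()) {
  k <- length(categories)
  n_col <- matrix(0L, k, k, dimnames = list(categories, categories))
  n_coex <- matrix(0L, k, k, dimnames = list(categories, categories))
  for (g in genome_ids) {
    rows <- catalogue[catalogue$genome_id == g, , drop = FALSE]
    if (nrow(rows) == 0L) next
    cats <- strsplit(rows$categories, ";", fixed = TRUE)
    for (a in seq_len(k)) for (b in a:k) {
      ia <- which(vapply(cats, function(x) categories[a] %in% x, logical(1)))
      ib <- which(vapply(cats, function(x) categories[b] %in% x, logical(1)))
      if (length(ia) == 0L || length(ib) == 0L) next
      n_coex[a, b] <- n_coex[a, b] + 1L
      found <- FALSE
      for (i in ia) for (j in ib) {
        if (i == j) {
          # one fusion gene covering both categories of a distinct pair
          if (a != b &&
              rows$end[i] - rows$start[i] + 1 < window_bp) found <- TRUE
        } else if (rows$contig_id[i] == rows$contig_id[j]) {
          span <- max(rows$end[i], rows$end[j]) -
            min(rows$start[i], rows$start[j]) + 1
          if (span < window_bp) found <- TRUE
        }
      }
      if (found) n_col[a, b] <- n_col[a, b] + 1L
    }
  }
  n_col[lower.tri(n_col)] <- t(n_col)[lower.tri(n_col)]
  n_coex[lower.tri(n_coex)] <- t(n_coex)[lower.tri(n_coex)]
  list(fraction = ifelse(n_coex > 0, n_col / n_coex, NA_real_),
       n_colocated = n_col, n_coexisting = n_coex)
}

# Random small genome set for oracle-equivalence checks: <= max_genomes
# genomes, <= max_genes catalogued genes each, categories drawn at random,
# coordinates spanning both sides of the 10 kb window.
random_catalogue <- function(max_genomes = 5L, max_genes = 15L,
                             categories = escrt_categories()) {
  n_genomes <- sample.int(max_genomes, 1L)
  genome_ids <- sprintf("R%02d", seq_len(n_genomes))
  rows <- NULL
  for (g in genome_ids) {
    n <- sample.int(max_genes, 1L)
    for (i in seq_len(n)) {
      start <- sample.int(40000L, 1L)
      len <- sample(200:1500, 1L)
      n_cat <- sample(1:2, 1L, prob = c(0.85, 0.15))
      cats <- sample(categories, n_cat)
      rows <- rbind(rows, make_entry(
        sprintf("%s_g%02d", g, i), start, start + len - 1L, cats,
        genome_id = g, contig_id = sample(c("c1", "c1", "c2"), 1L)))
    }
  }
  list(genome_ids = genome_ids, catalogue = rows)
}

# Independent RBH oracle: mutual argmax by direct enumeration.
naive_rbh <- function(hits_ab, hits_ba, evalue_max = 1e-5) {
  best_of <- function(hits, q) {
    h <- hits[hits$query_id == q & hits$evalue < evalue_max, , drop = FALSE]
    if (nrow(h) == 0L) return(NA_character_)
    h <- h[order(-h$bitscore, h$evalue, h$subject_id), , drop = FALSE]
    h$subject_id[1L]
  }
  pairs <- NULL
  for (q in unique(hits_ab$query_id)) {
    b <- best_of(hits_ab, q)
    if (!is.na(b) && identical(best_of(hits_ba, b), q)) {
      pairs <- rbind(pairs, data.frame(protein_a = q, protein_b = b,
                                       stringsAsFactors = FALSE))
    }
  }
  if (is.null(pairs)) {
    pairs <- data.frame(protein_a = character(), protein_b = character())
  }
  pairs[order(pairs$protein_a), , drop = FALSE]
}

hit_row <- function(q, s, bitscore, evalue = 1e-20) {
  data.frame(query_id = q, subject_id = s, bitscore = bitscore,
             evalue = evalue, stringsAsFactors = FALSE)
}

aa_msa <- function(...) {
  seqs <- c(...)
  if (is.null(names(seqs))) names(seqs) <- sprintf("s%d", seq_along(seqs))
  Biostrings::AAStringSet(seqs)
}
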