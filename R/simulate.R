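#' Configuration for the genome-set simulator
#'
#' Defines the statistical structure of a simulated genome set: every
#' genome carries one gene per functional category; with probability
#' `cluster_presence_prob` those genes sit together in a single compact
#' cluster (as observed in the most complete Asgard genomes), otherwise
#' they are scattered far apart on the contig. Decoy genes carry
#' non-diagnostic domain signatures; fusion events merge two adjacent
#' cluster genes into one gene carrying both categories' signatures; an
#' optional fragmentation step breaks the contig inside the cluster,
#' emulating metagenome-assembly contig boundaries.
#'
#' Defaults describe a compact, fully-populated cluster: gene lengths
#' uniform on 400-800 bp and intergenic gaps uniform on 20-150 bp keep a
#' full 12-gene cluster below 10 kb with overwhelming probability.
#' Scattered genes are separated by at least `scatter_spacing_bp`
#' (default 15 kb), i.e. they never co-locate under a 10 kb window.
#'
#' @param seed Integer seed; fixes all downstream randomness. Each genome
#'   draws from its own substream derived from this seed, so extending
#'   `n_genomes` does not perturb earlier genomes.
#' @param n_genomes Number of genomes in the set.
#' @param categories Functional categories each genome carries (default
#'   all 12).
#' @param cluster_presence_prob Probability that a genome's category genes
#'   are clustered (default 0.7).
#' @param cluster_inclusion_prob Probability that a given category's gene
#'   sits inside the cluster when the cluster is present (default 1).
#' @param gene_length_bp Length-2 numeric: uniform range of gene lengths.
#' @param intergenic_gap_bp Length-2 numeric: uniform range of in-cluster
#'   intergenic gaps.
#' @param scatter_spacing_bp Minimum spacing between scattered genes.
#' @param n_decoy_genes Number of non-diagnostic decoy genes per genome.
#' @param fusion_prob Probability that a pair of adjacent cluster genes is
#'   emitted as one fusion gene carrying both signatures (default 0.1).
#' @param fragmentation_prob Probability that a contig break is placed
#'   inside the cluster (default 0: closed genomes; raise it to emulate
#'   fragmented metagenome assemblies).
#' @param ortholog_mutation_rate Per-site substitution probability used by
#'   [simulate_ortholog_families()] (default 0.05).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genomes = 20L,
                       categories = escrt_categories(),
                       cluster_presence_prob = 0.7,
                       cluster_inclusion_prob = 1,
                       gene_length_bp = c(400, 800),
                       intergenic_gap_bp = c(20, 150),
                       scatter_spacing_bp = 15000,
                       n_decoy_genes = 10L,
                       fusion_prob = 0.1,
                       fragmentation_prob = 0,
                       ortholog_mutation_rate = 0.05) {
  probs <- c(cluster_presence_prob, cluster_inclusion_prob, fusion_prob,
             fragmentation_prob, ortholog_mutation_rate)
  stopifnot(all(probs >= 0 & probs <= 1), n_genomes >= 1L,
            length(gene_length_bp) == 2L, length(intergenic_gap_bp) == 2L,
            gene_length_bp[1L] > 0, scatter_spacing_bp > 0)
  structure(as.list(environment()), class = "sim_config")
}

# per-genome substream: a deterministic 32-bit seed derived from the master
# seed and the substream index, so substreams are stable when n grows
substream_seed <- function(seed, index, salt = 0L) {
  (as.numeric(seed) * 48271 + index * 16807 + salt * 69621) %% 2147483647
}

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(n) paste(sample(AA_LETTERS, n, replace = TRUE),
                                    collapse = "")

#' Simulate a genome set with planted ubiquitin/ESCRT clusters
#'
#' Generates genes, domain annotations, protein sequences and contig
#' lengths for `cfg$n_genomes` genomes, together with the ground truth of
#' what was planted. Each category's gene carries the first diagnostic
#' InterPro accession of that category; decoys carry reserved `IPR9xxxxx`
#' accessions that can never collide with the diagnostic table.
#'
#' @param cfg A [sim_config()].
#' @return List of class `genome_set_sim` with elements `genes` (data
#'   frame across all genomes), `domain_hits` (InterProScan-shaped hit
#'   table), `proteins` (named character vector of amino-acid sequences),
#'   `contigs` (data frame `genome_id`, `contig_id`, `length`),
#'   `genome_ids`, `truth` (per-genome list: `has_cluster`, `fragmented`,
#'   `assignments` data frame mapping category to gene and cluster
#'   membership) and `config`.
#' @export
simulate_genome_set <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  map <- default_diagnostic_map()
  cat_ipr <- vapply(cfg$categories, function(cc) {
    ids <- map$interpro_id[map$category == cc]
    if (length(ids) == 0L) stop("no diagnostic accession for category ", cc)
    ids[[1L]]
  }, character(1))
  genome_ids <- sprintf("sim%03d", seq_len(cfg$n_genomes))
  all_genes <- list(); all_hits <- list(); all_ctg <- list()
  proteins <- character(0); truth <- list()
  for (gi in seq_len(cfg$n_genomes)) {
    g <- genome_ids[[gi]]
    set.seed(substream_seed(cfg$seed, gi))
    has_cluster <- stats::runif(1) < cfg$cluster_presence_prob
    in_cluster <- if (has_cluster) {
      stats::runif(length(cfg$categories)) < cfg$cluster_inclusion_prob
    } else {
      rep(FALSE, length(cfg$categories))
    }
    clustered <- sample(cfg$categories[in_cluster])
    scattered <- cfg$categories[!cfg$categories %in% clustered]
    glen <- function() round(stats::runif(1, cfg$gene_length_bp[1L],
                                          cfg$gene_length_bp[2L]))
    ggap <- function() round(stats::runif(1, cfg$intergenic_gap_bp[1L],
                                          cfg$intergenic_gap_bp[2L]))
    genes <- NULL; hits <- NULL; assigns <- NULL
    gene_n <- 0L
    add_gene <- function(start, end, cats, decoy = FALSE) {
      gene_n <<- gene_n + 1L
      gid <- sprintf("%s_g%03d", g, gene_n)
      pid <- sprintf("%s_p%03d", g, gene_n)
      genes <<- rbind(genes, data.frame(
        gene_id = gid, genome_id = g, contig_id = "c1",
        start = start, end = end,
        strand = sample(c("+", "-"), 1L), protein_id = pid,
        stringsAsFactors = FALSE))
      plen <- max(50L, (end - start + 1L) %/% 3L - 1L)
      proteins[[pid]] <<- random_protein(plen)
      if (decoy) {
        ipr <- sprintf("IPR9%05d", sample.int(99999L, 1L))
        hits <<- rbind(hits, data.frame(
          protein_id = pid, interpro_id = ipr, aa_start = 1L,
          aa_end = plen, evalue = 1e-20, stringsAsFactors = FALSE))
      } else {
        for (cc in cats) {
          hits <<- rbind(hits, data.frame(
            protein_id = pid, interpro_id = cat_ipr[[cc]], aa_start = 1L,
            aa_end = plen, evalue = 1e-20, stringsAsFactors = FALSE))
        }
      }
      gid
    }
    # --- cluster genes, laid out left to right from a fixed offset
    cursor <- 1001
    i <- 1L
    while (i <= length(clustered)) {
      fuse <- i < length(clustered) && stats::runif(1) < cfg$fusion_prob
      cats <- if (fuse) clustered[i:(i + 1L)] else clustered[[i]]
      len <- glen()
      gid <- add_gene(cursor, cursor + len - 1L, cats)
      assigns <- rbind(assigns, data.frame(
        category = cats, gene_id = gid, in_cluster = TRUE,
        is_fusion = fuse, stringsAsFactors = FALSE))
      cursor <- cursor + len - 1L + ggap()
      i <- i + if (fuse) 2L else 1L
    }
    cluster_end <- cursor
    # --- scattered category genes, each >= scatter_spacing apart
    cursor <- cluster_end + cfg$scatter_spacing_bp
    for (cc in scattered) {
      len <- glen()
      gid <- add_gene(cursor, cursor + len - 1L, cc)
      assigns <- rbind(assigns, data.frame(
        category = cc, gene_id = gid, in_cluster = FALSE,
        is_fusion = FALSE, stringsAsFactors = FALSE))
      cursor <- cursor + len - 1L + cfg$scatter_spacing_bp
    }
    # --- decoy genes in the scattered zone
    for (d in seq_len(cfg$n_decoy_genes)) {
      len <- glen()
      add_gene(cursor, cursor + len - 1L, character(0), decoy = TRUE)
      cursor <- cursor + len - 1L + cfg$scatter_spacing_bp
    }
    contig_len <- cursor + 500
    # --- optional contig break inside the cluster
    fragmented <- FALSE
    cluster_rows <- which(genes$gene_id %in%
                            assigns$gene_id[assigns$in_cluster])
    if (cfg$fragmentation_prob > 0 && length(cluster_rows) >= 2L &&
        stats::runif(1) < cfg$fragmentation_prob) {
      fragmented <- TRUE
      candidates <- cluster_rows[-length(cluster_rows)]
      cut_after <- candidates[sample.int(length(candidates), 1L)]
      break_pos <- genes$end[cut_after] + 1L  # break in the following gap
      move <- genes$start > break_pos
      shift <- break_pos
      genes$contig_id[move] <- "c2"
      genes$start[move] <- genes$start[move] - shift
      genes$end[move] <- genes$end[move] - shift
      ctg <- data.frame(genome_id = g, contig_id = c("c1", "c2"),
                        length = c(break_pos, contig_len - shift),
                        stringsAsFactors = FALSE)
    } else {
      ctg <- data.frame(genome_id = g, contig_id = "c1",
                        length = contig_len, stringsAsFactors = FALSE)
    }
    all_genes[[g]] <- genes
    all_hits[[g]] <- hits
    all_ctg[[g]] <- ctg
    truth[[g]] <- list(has_cluster = has_cluster, fragmented = fragmented,
                       cluster_span = if (has_cluster)
                         c(1001, cluster_end) else NULL,
                       assignments = assigns)
  }
  empty_genes <- data.frame(
    gene_id = character(), genome_id = character(), contig_id = character(),
    start = integer(), end = integer(), strand = character(),
    protein_id = character(), stringsAsFactors = FALSE)
  structure(list(
    genes = do.call(rbind, c(list(empty_genes), unname(all_genes))),
    domain_hits = do.call(rbind, unname(all_hits)),
    proteins = proteins,
    contigs = do.call(rbind, unname(all_ctg)),
    genome_ids = genome_ids,
    truth = truth,
    config = cfg
  ), class = "genome_set_sim")
}

#' Catalogue a simulated genome set
#'
#' Convenience wrapper: classifies the simulated domain hits with the
#' default diagnostic map and joins them onto the simulated genes.
#'
#' @param sim A `genome_set_sim` from [simulate_genome_set()].
#' @param ... Passed to [classify_proteins()] (e.g. `expand_composite`).
#' @return Catalogue data frame (see [build_catalogue()]).
#' @export
catalogue_simulation <- function(sim, ...) {
  build_catalogue(sim$genes, classify_proteins(sim$domain_hits, ...))
}

#' Write a simulated genome set to files
#'
#' Emits, per genome, a GFF3 file (with `##sequence-region` pragmas), an
#' InterProScan-style 15-column TSV, and a protein FASTA; plus a contig
#' length TSV and the ground truth as JSON. Output is byte-deterministic
#' given the same simulation object.
#'
#' @param sim A `genome_set_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genome_set <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(sim$domain_hits)) {
    sim$domain_hits <- data.frame(protein_id = character(),
                                  interpro_id = character(),
                                  aa_start = integer(), aa_end = integer(),
                                  evalue = numeric(), stringsAsFactors = FALSE)
  }
  for (g in sim$genome_ids) {
    genes <- sim$genes[sim$genes$genome_id == g, , drop = FALSE]
    ctg <- sim$contigs[sim$contigs$genome_id == g, , drop = FALSE]
    gff <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", ctg$contig_id, ctg$length),
             sprintf("%s\tescrtscan_sim\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;protein_id=%s",
                     genes$contig_id, genes$start, genes$end, genes$strand,
                     genes$gene_id, genes$protein_id))
    writeLines(gff, file.path(dir, paste0(g, ".gff3")))
    hits <- sim$domain_hits[sim$domain_hits$protein_id %in% genes$protein_id, ,
                            drop = FALSE]
    plen <- nchar(sim$proteins[hits$protein_id])
    tsv <- sprintf("%s\tmd5\t%d\tSIM\tSIM%s\tsimulated signature\t%d\t%d\t%.1e\tT\t2020-12-05\t%s\tsimulated entry\t-\t-",
                   hits$protein_id, plen, sub("^IPR", "", hits$interpro_id),
                   hits$aa_start, hits$aa_end, hits$evalue, hits$interpro_id)
    writeLines(tsv, file.path(dir, paste0(g, ".iprscan.tsv")))
    prot <- sim$proteins[genes$protein_id]
    writeLines(as.vector(rbind(paste0(">", names(prot)), prot)),
               file.path(dir, paste0(g, ".faa")))
  }
  utils::write.table(sim$contigs, file.path(dir, "contig_lengths.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Simulate ortholog families across genomes
#'
#' Each family has one random root protein; every genome receives a copy
#' with independent per-site substitutions at
#' `cfg$ortholog_mutation_rate`. All cross-genome copies of a family are
#' true orthologs; the truth pair table lists every such pair.
#'
#' @param cfg A [sim_config()] (uses `seed`, `n_genomes`,
#'   `ortholog_mutation_rate`).
#' @param n_families Number of families.
#' @param family_length Root protein length in residues.
#' @return List with `sequences` (list per genome of named protein
#'   vectors) and `truth_pairs` (data frame `family`, `genome_a`,
#'   `protein_a`, `genome_b`, `protein_b`).
#' @export
simulate_ortholog_families <- function(cfg = sim_config(), n_families = 5L,
                                       family_length = 120L) {
  stopifnot(cfg$ortholog_mutation_rate < 0.5)
  genome_ids <- sprintf("sim%03d", seq_len(cfg$n_genomes))
  seqs <- stats::setNames(
    replicate(cfg$n_genomes, character(0), simplify = FALSE), genome_ids)
  pairs <- NULL
  for (f in seq_len(n_families)) {
    set.seed(substream_seed(cfg$seed, f, salt = 7L))
    root <- sample(AA_LETTERS, family_length, replace = TRUE)
    ids <- character(cfg$n_genomes)
    for (gi in seq_len(cfg$n_genomes)) {
      mutate <- stats::runif(family_length) < cfg$ortholog_mutation_rate
      copy <- root
      if (any(mutate)) {
        copy[mutate] <- sample(AA_LETTERS, sum(mutate), replace = TRUE)
      }
      id <- sprintf("%s_fam%02d", genome_ids[[gi]], f)
      ids[[gi]] <- id
      seqs[[gi]][[id]] <- paste(copy, collapse = "")
    }
    if (cfg$n_genomes >= 2L) {
      cmb <- utils::combn(cfg$n_genomes, 2L)
      pairs <- rbind(pairs, data.frame(
        family = f,
        genome_a = genome_ids[cmb[1L, ]], protein_a = ids[cmb[1L, ]],
        genome_b = genome_ids[cmb[2L, ]], protein_b = ids[cmb[2L, ]],
        stringsAsFactors = FALSE))
    }
  }
  list(sequences = seqs, truth_pairs = pairs)
}

#' Simulate an alignment with exact gap fractions
#'
#' Builds an alignment whose realised per-column (or per-sequence) gap
#' fractions equal the requested ones exactly, for boundary testing of
#' [trim_columns()] and [filter_sequences()]. Exactly one of
#' `col_gap_fracs` and `seq_gap_fracs` must be given; the requested
#' fractions must be representable as integer counts. Gaps are spread
#' round-robin across sequences (or columns) so the complementary
#' fractions stay balanced.
#'
#' @param n_seqs,n_cols Alignment dimensions.
#' @param col_gap_fracs Numeric vector of length `n_cols`: target gap
#'   fraction of each column.
#' @param seq_gap_fracs Numeric vector of length `n_seqs`: target gap
#'   fraction of each sequence.
#' @param seed Integer seed for the residue fill.
#' @return List with `msa` (`AAStringSet`), `col_gap_frac` and
#'   `seq_gap_frac` (realised fractions).
#' @export
simulate_msa <- function(n_seqs, n_cols, col_gap_fracs = NULL,
                         seq_gap_fracs = NULL, seed = 1L) {
  if (is.null(col_gap_fracs) == is.null(seq_gap_fracs)) {
    stop("give exactly one of col_gap_fracs or seq_gap_fracs")
  }
  set.seed(substream_seed(seed, 1L, salt = 13L))
  m <- matrix(sample(AA_LETTERS, n_seqs * n_cols, replace = TRUE),
              nrow = n_seqs)
  place <- function(n_slots, frac, what) {
    cnt <- frac * n_slots
    if (any(abs(cnt - round(cnt)) > 1e-9)) {
      stop("requested ", what, " gap fraction(s) not achievable with ",
           n_slots, " ", what, "s")
    }
    as.integer(round(cnt))
  }
  if (!is.null(col_gap_fracs)) {
    stopifnot(length(col_gap_fracs) == n_cols)
    counts <- place(n_seqs, col_gap_fracs, "sequence")
    offset <- 0L
    for (j in seq_len(n_cols)) {
      if (counts[j] > 0L) {
        rows <- ((offset + seq_len(counts[j]) - 1L) %% n_seqs) + 1L
        m[rows, j] <- "-"
        offset <- offset + counts[j]
      }
    }
  } else {
    stopifnot(length(seq_gap_fracs) == n_seqs)
    counts <- place(n_cols, seq_gap_fracs, "column")
    offset <- 0L
    for (i in seq_len(n_seqs)) {
      if (counts[i] > 0L) {
        cols <- ((offset + seq_len(counts[i]) - 1L) %% n_cols) + 1L
        m[i, cols] <- "-"
        offset <- offset + counts[i]
      }
    }
  }
  msa <- Biostrings::AAStringSet(apply(m, 1L, paste, collapse = ""))
  names(msa) <- sprintf("seq%03d", seq_len(n_seqs))
  list(msa = msa,
       col_gap_frac = unname(colMeans(m == "-")),
       seq_gap_frac = unname(rowMeans(m == "-")))
}
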