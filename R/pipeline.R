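#' Run the genomic survey pipeline end to end
#'
#' Chains the survey stages in order -- catalogue (GFF3 + InterProScan TSV
#' -> gene catalogue), co-location (catalogue -> fraction matrix per genome
#' set), synteny (catalogue -> regions, and RBH links when BLAST tables are
#' supplied) -- and writes `catalogue.tsv`, one `matrix.<set>.tsv` and
#' `colocation.<set>.tsv` per set, `regions.bed`, optionally `links.tsv`,
#' and a `manifest.json` recording tool version, config hash, input
#' checksums and per-stage row counts.
#'
#' @param config Path to a YAML configuration file, or an equivalent named
#'   list. Recognised keys: `gff_dir` (directory of `<genome>.gff3` files),
#'   `iprscan_dir` (directory of `<genome>.iprscan.tsv` files; defaults to
#'   `gff_dir`), `out_dir`, `sets` (named list `set_id -> character vector
#'   of genome ids`; default one set `"all"` containing every genome),
#'   `window_bp` (default 10000), `flank_bp` (default 2000), `evalue_max`
#'   (default 1e-5), `expand_composite` (default `FALSE`), `blast`
#'   (optional list of lists with `genome_a`, `genome_b`, `ab`, `ba` BLAST
#'   tabular paths).
#' @param quiet Suppress stage log lines.
#' @return The manifest, invisibly (a named list; also written as JSON).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config_path <- NULL
  if (is.character(config)) {
    config_path <- config
    config <- yaml::read_yaml(config)
  }
  say <- function(stage, ...) {
    if (!quiet) message("[", stage, "] ", ...)
  }
  cfg <- utils::modifyList(
    list(iprscan_dir = config$gff_dir, window_bp = 10000, flank_bp = 2000,
         evalue_max = 1e-5, expand_composite = FALSE, sets = NULL,
         blast = NULL),
    config)
  for (key in c("gff_dir", "out_dir")) {
    if (is.null(cfg[[key]])) stop("pipeline config must name '", key, "'")
  }
  gff_files <- sort(list.files(cfg$gff_dir, pattern = "\\.gff3?$",
                               full.names = TRUE))
  if (length(gff_files) == 0L) {
    stop("no GFF3 files found in ", cfg$gff_dir)
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    tool = "escrtscan",
    version = as.character(utils::packageVersion("escrtscan")),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = cfg[setdiff(names(cfg), "blast")],
    config_hash = if (!is.null(config_path))
      unname(tools::md5sum(config_path)) else NA_character_,
    inputs = as.list(tools::md5sum(gff_files)),
    stages = list()
  )

  # --- stage: catalogue -----------------------------------------------
  genes <- NULL; contig_lengths <- numeric(0); classifications <- list()
  for (gff in gff_files) {
    genome <- sub("\\.gff3?$", "", basename(gff))
    g <- read_genes_gff3(gff, genome_id = genome)
    cl <- attr(g, "contig_lengths")
    if (length(cl) > 0L) {
      contig_lengths[paste(genome, names(cl))] <- cl
    }
    genes <- rbind(genes, as.data.frame(g))
    ipr <- file.path(cfg$iprscan_dir, paste0(genome, ".iprscan.tsv"))
    if (file.exists(ipr)) {
      hits <- parse_interproscan_tsv(ipr)
      classifications <- c(classifications,
                           classify_proteins(
                             hits, expand_composite = cfg$expand_composite))
    }
  }
  catalogue <- build_catalogue(genes, classifications)
  write_catalogue(catalogue, file.path(cfg$out_dir, "catalogue.tsv"))
  genome_ids <- sort(unique(genes$genome_id))
  say("catalogue", nrow(genes), " genes read, ", nrow(catalogue),
      " catalogued across ", length(genome_ids), " genomes")
  manifest$stages$catalogue <- list(
    genes_read = nrow(genes), genes_catalogued = nrow(catalogue),
    genomes = length(genome_ids))

  # --- stage: colocation ----------------------------------------------
  sets <- cfg$sets
  if (is.null(sets)) sets <- list(all = genome_ids)
  coloc_cfg <- colocation_config(window_bp = cfg$window_bp)
  coloc_counts <- list()
  for (set_id in names(sets)) {
    m <- colocation_matrix(unlist(sets[[set_id]]), catalogue,
                           cfg = coloc_cfg, set_id = set_id)
    safe <- gsub("[^A-Za-z0-9._-]", "_", set_id)
    colocation_long(m, file.path(cfg$out_dir,
                                 paste0("colocation.", safe, ".tsv")))
    write_colocation_matrix(m, file.path(cfg$out_dir,
                                         paste0("matrix.", safe, ".tsv")))
    up <- upper.tri(m$fraction, diag = TRUE)
    coloc_counts[[set_id]] <- list(
      genomes = length(unlist(sets[[set_id]])),
      cells_defined = sum(!is.na(m$fraction[up])),
      cells_na = sum(is.na(m$fraction[up])))
    say("colocation", "set '", set_id, "': ",
        coloc_counts[[set_id]]$cells_defined, " defined cells, ",
        coloc_counts[[set_id]]$cells_na, " NA")
  }
  manifest$stages$colocation <- coloc_counts

  # --- stage: synteny --------------------------------------------------
  syn_cfg <- synteny_config(flank_bp = cfg$flank_bp,
                            evalue_max = cfg$evalue_max)
  all_regions <- list()
  bed <- NULL
  for (genome in genome_ids) {
    cat_g <- catalogue[catalogue$genome_id == genome, , drop = FALSE]
    if (nrow(cat_g) == 0L) next
    cl <- contig_lengths[paste(genome, unique(cat_g$contig_id))]
    names(cl) <- sub("^[^ ]+ ", "", names(cl))
    reg <- extract_regions(genes[genes$genome_id == genome, , drop = FALSE],
                           cat_g, cl, cfg = syn_cfg)
    all_regions[[genome]] <- reg
    bed <- rbind(bed, reg$regions)
  }
  regions_to_bed(bed, file.path(cfg$out_dir, "regions.bed"))
  say("synteny", nrow(bed), " regions across ", length(all_regions),
      " genomes")
  manifest$stages$synteny <- list(regions = nrow(bed))

  links <- NULL; n_rbh <- 0L
  if (!is.null(cfg$blast)) {
    for (b in cfg$blast) {
      rbh <- reciprocal_best_hits(read_blast_tabular(b$ab),
                                  read_blast_tabular(b$ba), cfg = syn_cfg)
      n_rbh <- n_rbh + nrow(rbh)
      lk <- synteny_links(all_regions[[b$genome_a]],
                          all_regions[[b$genome_b]], rbh)
      if (nrow(lk) > 0L) {
        lk$genome_a <- b$genome_a
        lk$genome_b <- b$genome_b
        links <- rbind(links, lk)
      }
    }
    if (is.null(links)) {
      links <- data.frame(region_a = character(), gene_a = character(),
                          protein_a = character(), region_b = character(),
                          gene_b = character(), protein_b = character())
    }
    utils::write.table(links, file.path(cfg$out_dir, "links.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    say("synteny", n_rbh, " RBH pairs, ", nrow(links), " links in regions")
    manifest$stages$synteny$rbh_pairs <- n_rbh
    manifest$stages$synteny$links <- nrow(links)
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
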