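test_that("flank windows are drawn, clipped and merged correctly", {
  cfg <- synteny_config(flank_bp = 2000)
  # plain window, no clipping
  genes <- make_gene("g1", 5000, 6000)
  catal <- make_entry("g1", 5000, 6000, "Vps25")
  reg <- extract_regions(genes, catal, c(c1 = 20000), cfg)$regions
  expect_equal(c(reg$start, reg$end), c(3000, 8000))
  expect_false(reg$clipped_left || reg$clipped_right)
  # clipped at the left contig boundary
  genes <- make_gene("g1", 500, 1500)
  catal <- make_entry("g1", 500, 1500, "Vps25")
  reg <- extract_regions(genes, catal, c(c1 = 10000), cfg)$regions
  expect_equal(c(reg$start, reg$end), c(1, 3500))
  expect_true(reg$clipped_left)
  expect_false(reg$clipped_right)
  # overlapping windows merge into one region
  genes <- rbind(make_gene("g1", 1000, 2000), make_gene("g2", 4000, 5000))
  catal <- rbind(make_entry("g1", 1000, 2000, "Vps25"),
                 make_entry("g2", 4000, 5000, "Vps28"))
  reg <- extract_regions(genes, catal, c(c1 = 8000), cfg)$regions
  expect_equal(nrow(reg), 1L)
  expect_equal(c(reg$start, reg$end), c(1, 7000))
  expect_true(reg$clipped_left)
})

test_that("region members include uncatalogued neighbours, not distant genes", {
  cfg <- synteny_config(flank_bp = 2000)
  genes <- rbind(make_gene("g1", 5000, 6000),
                 make_gene("g2", 7500, 7900),    # decoy inside the window
                 make_gene("g3", 15000, 15500))  # outside
  catal <- make_entry("g1", 5000, 6000, "ESCRT-III")
  out <- extract_regions(genes, catal, c(c1 = 20000), cfg)
  expect_equal(sort(out$members$gene_id), c("g1", "g2"))
  expect_equal(out$members$is_catalogued[order(out$members$gene_id)],
               c(TRUE, FALSE))
  expect_equal(out$regions$n_members, 2L)
})

test_that("unknown contig length is an error naming the contig", {
  catal <- make_entry("g1", 100, 200, "Vps25", contig_id = "cX")
  expect_error(extract_regions(make_gene("g1", 100, 200, contig_id = "cX"),
                               catal, c(c1 = 1000)), "cX")
})

test_that("emitted regions never overlap and re-merging is a fixed point", {
  set.seed(51)
  cfg <- synteny_config(flank_bp = 2000)
  for (i in 1:10) {
    n <- sample(2:8, 1L)
    starts <- sort(sample.int(30000L, n))
    genes <- do.call(rbind, lapply(seq_len(n), function(j) {
      make_gene(sprintf("g%d", j), starts[j], starts[j] + 500)
    }))
    catal <- genes
    catal$categories <- "Vps25"
    catal$is_fusion <- FALSE
    out <- extract_regions(genes, catal, c(c1 = 40000), cfg)
    reg <- out$regions
    if (nrow(reg) > 1L) {
      expect_true(all(reg$start[-1L] > reg$end[-nrow(reg)]))
    }
    # every region contains at least one catalogued gene
    expect_true(all(vapply(reg$region_id, function(r) {
      any(out$members$is_catalogued[out$members$region_id == r])
    }, logical(1))))
    # feeding the emitted regions back as zero-flank anchors changes nothing
    anchors <- reg
    anchors$gene_id <- reg$region_id
    anchors$strand <- "+"
    anchors$protein_id <- reg$region_id
    anchors$categories <- "Vps25"
    again <- extract_regions(anchors, anchors, c(c1 = 40000),
                             synteny_config(flank_bp = 0))$regions
    expect_equal(again[, c("start", "end")], reg[, c("start", "end")])
  }
})

test_that("reciprocal best hits require mutual argmax and the e-value cut", {
  cfg <- synteny_config()
  ab <- rbind(hit_row("a1", "b1", 200), hit_row("a1", "b2", 150))
  ba <- rbind(hit_row("b1", "a1", 200), hit_row("b2", "a1", 150))
  rbh <- reciprocal_best_hits(ab, ba, cfg)
  expect_equal(rbh$protein_a, "a1")
  expect_equal(rbh$protein_b, "b1")
  # a1 -> b1 but b1's best is a2: no pair
  ab <- hit_row("a1", "b1", 200)
  ba <- rbind(hit_row("b1", "a2", 300), hit_row("b1", "a1", 200))
  expect_equal(nrow(reciprocal_best_hits(ab, ba, cfg)), 0L)
  # one direction at e-value 1e-4 fails the strict 1e-5 threshold
  ab <- hit_row("a1", "b1", 200, evalue = 1e-20)
  ba <- hit_row("b1", "a1", 200, evalue = 1e-4)
  expect_equal(nrow(reciprocal_best_hits(ab, ba, cfg)), 0L)
  # exactly 1e-5 is excluded too ("lower than")
  ba$evalue <- 1e-5
  expect_equal(nrow(reciprocal_best_hits(ab, ba, cfg)), 0L)
  expect_equal(nrow(reciprocal_best_hits(
    ab[0, ], ba[0, ], cfg)), 0L)
})

test_that("RBH ties break by bitscore, then e-value, then subject id", {
  cfg <- synteny_config()
  ab <- rbind(hit_row("a1", "b2", 100, 1e-30),
              hit_row("a1", "b1", 100, 1e-30))
  ba <- rbind(hit_row("b1", "a1", 100), hit_row("b2", "a1", 100))
  rbh <- reciprocal_best_hits(ab, ba, cfg)
  expect_equal(rbh$protein_b, "b1")  # lexicographic tie-break
  ab <- rbind(hit_row("a1", "b2", 100, 1e-40),
              hit_row("a1", "b1", 100, 1e-30))
  rbh <- reciprocal_best_hits(ab, ba, cfg)
  expect_equal(rbh$protein_b, "b2")  # lower e-value wins at equal bitscore
})

test_that("RBH equals brute-force mutual argmax and is direction-symmetric", {
  set.seed(61)
  cfg <- synteny_config()
  for (i in 1:10) {
    na <- sample.int(20L, 1L); nb <- sample.int(20L, 1L)
    a_ids <- sprintf("a%02d", seq_len(na))
    b_ids <- sprintf("b%02d", seq_len(nb))
    mk <- function(q_ids, s_ids) {
      n <- sample.int(60L, 1L)
      data.frame(query_id = sample(q_ids, n, replace = TRUE),
                 subject_id = sample(s_ids, n, replace = TRUE),
                 bitscore = sample(50:300, n, replace = TRUE),
                 evalue = 10^-sample(2:40, n, replace = TRUE),
                 stringsAsFactors = FALSE)
    }
    ab <- mk(a_ids, b_ids); ba <- mk(b_ids, a_ids)
    rbh <- reciprocal_best_hits(ab, ba, cfg)
    oracle <- naive_rbh(ab, ba)
    expect_equal(rbh[, c("protein_a", "protein_b")], oracle,
                 ignore_attr = TRUE)
    # swapping directions gives the same unordered pair set
    swapped <- reciprocal_best_hits(ba, ab, cfg)
    expect_setequal(paste(rbh$protein_a, rbh$protein_b),
                    paste(swapped$protein_b, swapped$protein_a))
  }
})

test_that("local alignment scores match the BLOSUM62 diagonal on identity", {
  set.seed(71)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  aa <- rownames(BLOSUM62)[1:20]
  seq50 <- paste(sample(aa, 50, replace = TRUE), collapse = "")
  hit <- pairwise_similarity(seq50, seq50)
  expected <- sum(diag(BLOSUM62)[match(strsplit(seq50, "")[[1]], aa)])
  expect_equal(hit$score, expected)
  # symmetry
  other <- paste(sample(aa, 60, replace = TRUE), collapse = "")
  expect_equal(pairwise_similarity(seq50, other)$score,
               pairwise_similarity(other, seq50)$score)
  # empty sequence scores zero; invalid characters are rejected
  expect_equal(pairwise_similarity("", seq50)$score, 0)
  expect_error(pairwise_similarity("ACDB1", seq50), "non-canonical")
})

test_that("bitscore and e-value follow the Karlin-Altschul conversion", {
  hit <- pairwise_similarity("MKW", "MKW")
  raw <- hit$score
  expect_equal(hit$bitscore, (0.267 * raw - log(0.041)) / log(2))
  expect_equal(hit$evalue, 9 * 2^(-hit$bitscore))
})

test_that("planted orthologs are recovered as RBHs via the built-in aligner", {
  fam <- simulate_ortholog_families(
    sim_config(seed = 9, n_genomes = 2, ortholog_mutation_rate = 0.1),
    n_families = 8, family_length = 100)
  ab <- similarity_search(fam$sequences[[1]], fam$sequences[[2]])
  ba <- similarity_search(fam$sequences[[2]], fam$sequences[[1]])
  rbh <- reciprocal_best_hits(ab, ba)
  found <- paste(rbh$protein_a, rbh$protein_b)
  truth <- paste(fam$truth_pairs$protein_a, fam$truth_pairs$protein_b)
  expect_gte(mean(truth %in% found), 0.95)
})

test_that("links join RBH pairs to region members and count drops", {
  cfg <- synteny_config(flank_bp = 2000)
  genes_a <- rbind(make_gene("ga1", 5000, 6000, genome_id = "A"),
                   make_gene("ga2", 40000, 41000, genome_id = "A"))
  catal_a <- make_entry("ga1", 5000, 6000, "Vps25", genome_id = "A")
  regs_a <- extract_regions(genes_a, catal_a, c(c1 = 50000), cfg)
  genes_b <- make_gene("gb1", 9000, 9900, genome_id = "B")
  catal_b <- make_entry("gb1", 9000, 9900, "Vps25", genome_id = "B")
  regs_b <- extract_regions(genes_b, catal_b, c(c1 = 20000), cfg)
  rbh <- data.frame(protein_a = c("ga1_p", "ga2_p"),
                    protein_b = c("gb1_p", "gb1_p"),
                    bitscore_ab = c(200, 150), bitscore_ba = c(200, 150),
                    stringsAsFactors = FALSE)
  links <- synteny_links(regs_a, regs_b, rbh)
  expect_equal(nrow(links), 1L)
  expect_equal(links$gene_a, "ga1")
  expect_equal(links$gene_b, "gb1")
  expect_equal(attr(links, "n_dropped"), 1L)  # ga2 is outside all regions
  none <- synteny_links(regs_a, regs_b, rbh[0, ])
  expect_equal(nrow(none), 0L)
})

test_that("BED export converts to 0-based half-open coordinates", {
  genes <- make_gene("g1", 5000, 6000)
  catal <- make_entry("g1", 5000, 6000, "Vps25")
  reg <- extract_regions(genes, catal, c(c1 = 20000))$regions
  path <- tempfile(fileext = ".bed")
  regions_to_bed(reg, path)
  bed <- utils::read.delim(path, header = FALSE)
  expect_equal(bed$V2, 2999)  # 1-based 3000 -> 0-based 2999
  expect_equal(bed$V3, 8000)  # inclusive end 8000 -> half-open 8000
})
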