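test_that("pair_span is the minimal containing region length", {
  g1 <- list(genome_id = "G", contig_id = "c1", start = 100, end = 1099)
  g2 <- list(genome_id = "G", contig_id = "c1", start = 5000, end = 5999)
  expect_equal(pair_span(g1, g2), 5900)
  expect_equal(pair_span(g1, g1), 1000)  # identity: gene length
  g3 <- list(genome_id = "G", contig_id = "c2", start = 100, end = 1099)
  expect_true(is.na(pair_span(g1, g3)))
  g4 <- list(genome_id = "H", contig_id = "c1", start = 100, end = 1099)
  expect_error(pair_span(g1, g4), "genome")
})

test_that("tri-state co-location calls cover fusion, absence and distance", {
  cfg <- colocation_config()
  fusion <- make_entry("f1", 1000, 2499, c("Vps23/37", "Vps28"))
  expect_equal(genome_colocates(fusion, "Vps23/37", "Vps28", cfg), "colocated")
  one <- make_entry("g1", 1000, 1999, "Vps25")
  expect_equal(genome_colocates(one, "Vps25", "Vps28", cfg), "absent")
  far <- rbind(make_entry("g1", 1, 1000, "Vps25"),
               make_entry("g2", 50000, 50999, "ESCRT-III"))
  expect_equal(genome_colocates(far, "Vps25", "ESCRT-III", cfg),
               "coexisting_only")
  near <- rbind(make_entry("g1", 1, 1000, "Vps25"),
                make_entry("g2", 5000, 5999, "ESCRT-III"))
  expect_equal(genome_colocates(near, "Vps25", "ESCRT-III", cfg), "colocated")
})

test_that("same-category co-location needs two distinct genes", {
  cfg <- colocation_config()
  single <- make_entry("g1", 1000, 1999, "ESCRT-III")
  expect_equal(genome_colocates(single, "ESCRT-III", "ESCRT-III", cfg),
               "coexisting_only")
  pair <- rbind(make_entry("g1", 1000, 1999, "ESCRT-III"),
                make_entry("g2", 3000, 3999, "ESCRT-III"))
  expect_equal(genome_colocates(pair, "ESCRT-III", "ESCRT-III", cfg),
               "colocated")
})

test_that("fusion counting and window boundary are configurable", {
  fusion <- make_entry("f1", 1000, 2499, c("Vps23/37", "Vps28"))
  no_fusion <- colocation_config(count_fusion_as_colocated = FALSE)
  expect_equal(genome_colocates(fusion, "Vps23/37", "Vps28", no_fusion),
               "coexisting_only")
  # span exactly at the window is NOT co-located (strict "less than")
  at <- rbind(make_entry("g1", 1, 1000, "Vps25"),
              make_entry("g2", 9001, 10000, "ESCRT-III"))
  expect_equal(genome_colocates(at, "Vps25", "ESCRT-III",
                                colocation_config(window_bp = 10000)),
               "coexisting_only")
  expect_equal(genome_colocates(at, "Vps25", "ESCRT-III",
                                colocation_config(window_bp = 10001)),
               "colocated")
})

test_that("nearest-edge gap measure is available as an alternative", {
  cfg_gap <- colocation_config(window_bp = 5000, measure = "gap")
  cfg_region <- colocation_config(window_bp = 5000)
  entries <- rbind(make_entry("g1", 1, 4000, "Vps25"),
                   make_entry("g2", 6000, 9999, "ESCRT-III"))
  # region span 9999 >= 5000 but edge gap 1999 < 5000
  expect_equal(genome_colocates(entries, "Vps25", "ESCRT-III", cfg_region),
               "coexisting_only")
  expect_equal(genome_colocates(entries, "Vps25", "ESCRT-III", cfg_gap),
               "colocated")
})

test_that("fractions count co-located over coexisting genomes", {
  catal <- rbind(
    make_entry("a1", 1, 1000, "Vps25", genome_id = "G1"),
    make_entry("a2", 3000, 3999, "ESCRT-III", genome_id = "G1"),
    make_entry("b1", 1, 1000, "Vps25", genome_id = "G2"),
    make_entry("b2", 4000, 4999, "ESCRT-III", genome_id = "G2"),
    make_entry("c1", 1, 1000, "Vps25", genome_id = "G3"),
    make_entry("c2", 50000, 50999, "ESCRT-III", genome_id = "G3"))
  m <- colocation_matrix(c("G1", "G2", "G3"), catal)
  expect_equal(m$fraction["Vps25", "ESCRT-III"], 2 / 3)
  expect_equal(m$n_coexisting["Vps25", "ESCRT-III"], 3L)
  # a pair never coexisting stays NA, distinct from 0
  expect_true(is.na(m$fraction["Vps4", "E1"]))
  expect_equal(m$n_coexisting["Vps4", "E1"], 0L)
  expect_error(colocation_matrix(character(0), catal), "empty")
})

test_that("matrix is exactly symmetric with fractions in [0, 1]", {
  set.seed(21)
  for (i in 1:5) {
    rc <- random_catalogue()
    m <- colocation_matrix(rc$genome_ids, rc$catalogue)
    expect_identical(m$fraction, t(m$fraction))
    expect_identical(m$n_colocated, t(m$n_colocated))
    ok <- is.na(m$fraction) | (m$fraction >= 0 & m$fraction <= 1)
    expect_true(all(ok))
    expect_true(all(m$n_colocated <= m$n_coexisting))
  }
})

test_that("matrix agrees with the brute-force oracle on random sets", {
  set.seed(31)
  for (i in 1:10) {
    rc <- random_catalogue()
    m <- colocation_matrix(rc$genome_ids, rc$catalogue)
    o <- naive_colocation_matrix(rc$genome_ids, rc$catalogue)
    expect_equal(m$fraction, o$fraction)
    expect_equal(m$n_colocated, o$n_colocated)
    expect_equal(m$n_coexisting, o$n_coexisting)
  }
})

test_that("fractions are non-decreasing in the window size", {
  set.seed(41)
  windows <- c(1000, 5000, 10000, 50000)
  for (i in 1:5) {
    rc <- random_catalogue()
    prev <- NULL
    for (w in windows) {
      m <- colocation_matrix(rc$genome_ids, rc$catalogue,
                             cfg = colocation_config(window_bp = w))
      if (!is.null(prev)) {
        both <- !is.na(prev) & !is.na(m$fraction)
        expect_true(all(m$fraction[both] >= prev[both]))
        # NA cells (never coexisting) do not depend on the window
        expect_identical(is.na(prev), is.na(m$fraction))
      }
      prev <- m$fraction
    }
  }
})

test_that("long export writes NA distinct from zero", {
  catal <- rbind(make_entry("a1", 1, 1000, "Vps25"),
                 make_entry("a2", 50000, 50999, "ESCRT-III"))
  m <- colocation_matrix("G1", catal)
  path <- tempfile(fileext = ".tsv")
  colocation_long(m, path)
  txt <- utils::read.delim(path, stringsAsFactors = FALSE)
  row_zero <- txt[txt$cat_a == "Vps25" & txt$cat_b == "ESCRT-III", ]
  expect_equal(row_zero$fraction, 0)          # coexisting but far apart
  row_na <- txt[txt$cat_a == "Vps4" & txt$cat_b == "E1", ]
  expect_true(is.na(row_na$fraction))         # never coexisting
})
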