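#' The twelve ubiquitin/ESCRT functional categories
#'
#' Role labels used throughout the package for genes diagnosed as encoding
#' components of the ubiquitin-ESCRT pathway: the ESCRT-I subunits
#' (`Vps23/37`, `Vps28`, and the composite `Vps23/37/28` signature found in
#' fusion-type architectures), the ESCRT-II subunits (`Vps22/36`, `Vps25`),
#' `ESCRT-III`, the `Vps4` AAA-ATPase, `Ubiquitin` itself, and the
#' ubiquitylation enzymes (`E1`, `E2`, `E3`) plus deubiquitinases (`DUB`).
#'
#' @return Character vector of the 12 category labels, in canonical display
#'   order (ESCRT-I, ESCRT-II, ESCRT-III/Vps4, then the ubiquitin system).
#' @export
#' @examples
#' escrt_categories()
escrt_categories <- function() {
  c("Vps23/37", "Vps28", "Vps23/37/28", "Vps22/36", "Vps25",
    "ESCRT-III", "Vps4", "Ubiquitin", "E1", "E2", "E3", "DUB")
}

#' Diagnostic InterPro domain table
#'
#' The default mapping from InterPro accessions to ubiquitin/ESCRT functional
#' categories. A protein carrying any of these signatures is classified into
#' the corresponding category; a protein carrying signatures from more than
#' one category is a candidate fusion gene. Each accession maps to exactly
#' one category.
#'
#' The table is deliberately plain data (two-column data frame) so that it
#' can be exported, edited, and re-loaded with [read_diagnostic_map()]:
#' InterPro signatures are versioned and users may need to extend or replace
#' entries as the database evolves.
#'
#' The composite `Vps23/37/28` signature is kept as its own category here;
#' see the `expand_composite` argument of [classify_protein()] to count it as
#' evidence for both `Vps23/37` and `Vps28` in co-location analyses.
#'
#' @return Data frame with columns `interpro_id` and `category`.
#' @export
#' @examples
#' map <- default_diagnostic_map()
#' table(map$category)
default_diagnostic_map <- function() {
  map <- data.frame(
    interpro_id = c(
      "IPR017916",                           # Vps23/37
      "IPR007143", "IPR037206",              # Vps28
      "IPR037202",                           # Vps23/37/28 composite
      "IPR016689", "IPR040608", "IPR021648", # Vps22/36
      "IPR008570", "IPR014041",              # Vps25
      "IPR005024",                           # ESCRT-III
      "IPR007330", "IPR031255", "IPR015415", # Vps4
      "IPR029071", "IPR000626",              # Ubiquitin
      "IPR000594",                           # E1
      "IPR000608", "IPR006575", "IPR016135", # E2
      "IPR018611",                           # E3
      "IPR000555"                            # DUB
    ),
    category = c(
      "Vps23/37",
      "Vps28", "Vps28",
      "Vps23/37/28",
      "Vps22/36", "Vps22/36", "Vps22/36",
      "Vps25", "Vps25",
      "ESCRT-III",
      "Vps4", "Vps4", "Vps4",
      "Ubiquitin", "Ubiquitin",
      "E1",
      "E2", "E2", "E2",
      "E3",
      "DUB"
    ),
    stringsAsFactors = FALSE
  )
  map
}

#' Read a diagnostic map from a TSV file
#'
#' @param path Tab-separated file with header columns `interpro_id` and
#'   `category`.
#' @return Data frame with columns `interpro_id` and `category`.
#' @export
read_diagnostic_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_diagnostic_map(map)
  map[, c("interpro_id", "category")]
}

#' Write a diagnostic map to a TSV file
#'
#' @param map Data frame as returned by [default_diagnostic_map()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_diagnostic_map <- function(map, path) {
  validate_diagnostic_map(map)
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_diagnostic_map <- function(map) {
  stopifnot(is.data.frame(map),
            all(c("interpro_id", "category") %in% names(map)))
  bad <- !grepl("^IPR[0-9]{6}$", map$interpro_id)
  if (any(bad)) {
    stop("malformed InterPro accession(s) in diagnostic map: ",
         paste(map$interpro_id[bad], collapse = ", "))
  }
  # an accession listed under two distinct categories would make
  # classification ambiguous
  dup <- unique(map$interpro_id[duplicated(map$interpro_id)])
  for (id in dup) {
    if (length(unique(map$category[map$interpro_id == id])) > 1L) {
      stop("InterPro accession ", id, " maps to more than one category")
    }
  }
  invisible(map)
}
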