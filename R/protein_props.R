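# Average isotopic residue masses (Da) of the 20 canonical amino acids,
# i.e. the monomer mass minus one water, as used by ProtParam. One water
# (18.01528 Da) is added back per chain.
AA_RESIDUE_MASS_AVG <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

# Monoisotopic residue masses (Da)
AA_RESIDUE_MASS_MONO <- c(
  A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
  E = 129.04259, Q = 128.05858, G = 57.02146, H = 137.05891, I = 113.08406,
  L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P = 97.05276,
  S = 87.03203, T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841)

WATER_MASS_AVG <- 18.01528
WATER_MASS_MONO <- 18.010565

#' Protein molecular weight from sequence
#'
#' Sum of residue masses plus one water per chain. Average isotopic masses
#' are the default (matching ProtParam and the usual comparison against SEC
#' and MALS mass estimates); monoisotopic masses are available behind a
#' flag. Non-canonical characters are an error naming the first offending
#' position.
#'
#' @param seq Amino-acid sequence (single string, canonical 20 letters).
#' @param monoisotopic Use monoisotopic instead of average masses.
#' @return Mass in Da.
#' @export
#' @examples
#' molecular_weight("G")  # free glycine, 75.07 Da
molecular_weight <- function(seq, monoisotopic = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) > 0L)
  chars <- strsplit(seq, "")[[1L]]
  masses <- if (monoisotopic) AA_RESIDUE_MASS_MONO else AA_RESIDUE_MASS_AVG
  idx <- match(chars, names(masses))
  if (anyNA(idx)) {
    pos <- which(is.na(idx))[1L]
    stop("invalid amino-acid character '", chars[pos], "' at position ", pos)
  }
  water <- if (monoisotopic) WATER_MASS_MONO else WATER_MASS_AVG
  sum(masses[idx]) + water
}

#' A280 extinction coefficient from sequence
#'
#' Molar extinction coefficient at 280 nm from tryptophan, tyrosine and
#' (optionally) cystine content, using the Pace coefficients ProtParam
#' applies: `5500 * nTrp + 1490 * nTyr + 125 * nCystine`, with the number
#' of cystines taken as `floor(nCys / 2)` when disulphides are assumed
#' formed. The mass-basis coefficient (absorbance of a 1 mg/ml solution in
#' a 1 cm cell) is the molar coefficient divided by the molecular weight.
#'
#' @param seq Amino-acid sequence (single string).
#' @param cystines_formed Assume all cysteine pairs form disulphides
#'   (default `FALSE`: reduced cysteines contribute nothing).
#' @return List with `molar` (M^-1 cm^-1), `mass_basis` ((mg/ml)^-1 cm^-1)
#'   and the counts `n_trp`, `n_tyr`, `n_cys`.
#' @export
extinction_coefficient_280 <- function(seq, cystines_formed = FALSE) {
  mw <- molecular_weight(seq)  # also validates the sequence
  chars <- strsplit(seq, "")[[1L]]
  n_trp <- sum(chars == "W")
  n_tyr <- sum(chars == "Y")
  n_cys <- sum(chars == "C")
  molar <- 5500 * n_trp + 1490 * n_tyr +
    (if (cystines_formed) 125 * (n_cys %/% 2L) else 0)
  list(molar = molar, mass_basis = molar / mw,
       n_trp = n_trp, n_tyr = n_tyr, n_cys = n_cys)
}

#' The six SEC calibration standards
#'
#' Standard proteins of a typical size-exclusion column calibration kit,
#' with their masses: carbonic anhydrase (29 kDa), bovine serum albumin
#' (66 kDa), alcohol dehydrogenase (150 kDa), beta-amylase (200 kDa),
#' apoferritin (443 kDa) and thyroglobulin (669 kDa). Elution volumes are
#' column- and run-specific and must be supplied by the user.
#'
#' @return Data frame with columns `name` and `mass_kda`.
#' @export
sec_standards <- function() {
  data.frame(
    name = c("carbonic anhydrase", "bovine serum albumin",
             "alcohol dehydrogenase", "beta-amylase", "apoferritin",
             "thyroglobulin"),
    mass_kda = c(29, 66, 150, 200, 443, 669),
    stringsAsFactors = FALSE
  )
}

#' Fit a SEC column calibration curve
#'
#' Ordinary least squares of `log10(mass [kDa])` on the normalised elution
#' volume `Ve/Vo`. A physically sensible column gives a negative slope
#' (larger proteins elute earlier).
#'
#' @param standards Data frame with columns `mass_kda` and `ve_ml` (and
#'   optionally `name`); at least two standards with distinct elution
#'   volumes are required.
#' @param vo_ml Column void volume in ml.
#' @return List of class `sec_calibration` with `slope`, `intercept`,
#'   `vo_ml`, `r_squared` and the underlying `lm` fit.
#' @export
fit_sec_calibration <- function(standards, vo_ml) {
  stopifnot(is.data.frame(standards),
            all(c("mass_kda", "ve_ml") %in% names(standards)),
            is.numeric(vo_ml), vo_ml > 0)
  if (nrow(standards) < 2L) stop("at least two calibration standards required")
  if (any(standards$mass_kda <= 0) || any(standards$ve_ml <= 0)) {
    stop("standard masses and elution volumes must be positive")
  }
  if (length(unique(standards$ve_ml)) < 2L) {
    stop("calibration standards must have distinct elution volumes")
  }
  dat <- data.frame(log_mass = log10(standards$mass_kda),
                    ve_vo = standards$ve_ml / vo_ml)
  fit <- stats::lm(log_mass ~ ve_vo, data = dat)
  sst <- sum((dat$log_mass - mean(dat$log_mass))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  structure(list(slope = unname(stats::coef(fit)[["ve_vo"]]),
                 intercept = unname(stats::coef(fit)[["(Intercept)"]]),
                 vo_ml = vo_ml, r_squared = r2, fit = fit),
            class = "sec_calibration")
}

#' @export
print.sec_calibration <- function(x, ...) {
  cat(sprintf(
    "SEC calibration: log10(mass kDa) = %.4f * Ve/Vo + %.4f (r^2 = %.4f)\n",
    x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Apparent mass from an elution volume
#'
#' Inverts a fitted calibration curve:
#' `10 ^ (slope * Ve/Vo + intercept)` in kDa.
#'
#' @param model A `sec_calibration` from [fit_sec_calibration()].
#' @param ve_ml Elution volume in ml (> 0).
#' @return Apparent mass in kDa.
#' @export
apparent_mass <- function(model, ve_ml) {
  stopifnot(inherits(model, "sec_calibration"))
  if (any(ve_ml <= 0)) stop("elution volume must be positive")
  10^(model$slope * (ve_ml / model$vo_ml) + model$intercept)
}

#' Per-sequence biophysical property table
#'
#' @param seqs Named character vector (or `AAStringSet`) of protein
#'   sequences.
#' @param cystines_formed Passed to [extinction_coefficient_280()].
#' @return Data frame with columns `id`, `mw_da`, `e280_molar`,
#'   `e280_mg_ml`.
#' @export
protein_property_table <- function(seqs, cystines_formed = FALSE) {
  if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
  stopifnot(length(names(seqs)) == length(seqs))
  rows <- lapply(names(seqs), function(id) {
    mw <- molecular_weight(seqs[[id]])
    e <- extinction_coefficient_280(seqs[[id]], cystines_formed)
    data.frame(id = id, mw_da = mw, e280_molar = e$molar,
               e280_mg_ml = e$mass_basis, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
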