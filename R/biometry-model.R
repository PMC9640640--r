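#' @keywords internal
"_PACKAGE"

# Plausibility ranges shared by validation and the generator.
.AL_RANGE <- c(15, 40)    # mm
.KM_RANGE <- c(30, 60)    # D
.POWER_RANGE <- c(-10, 40) # D

#' Axial-length measurement options
#'
#' The optical biometer displays an axial length (AL) under one of three
#' measurement modes: phakic (natural lens in place, the preoperative
#' setting), aphakic (no lens), and pseudophakic-acrylate (acrylic IOL in
#' place). The modes share the group refractive index and differ only in
#' the AL computation applied to the interferometry signal.
#'
#' @return Character vector of the three mode codes: `"Ph"`, `"Ap"`, `"Ps"`.
#' @export
al_options <- function() c("Ph", "Ap", "Ps")

.check_al_option <- function(option) {
  if (length(option) != 1L || !option %in% al_options()) {
    stop("unknown AL option '", paste(option, collapse = ","),
         "'; must be one of ", paste(al_options(), collapse = ", "),
         call. = FALSE)
  }
  option
}

#' Instrument measurement-mode offsets
#'
#' Additive model of the biometer's per-mode AL display. Offsets are
#' expressed relative to the pseudophakic display; `acrylate_correction`
#' is the constant the instrument adds to the raw optical reading when the
#' pseudophakic-acrylate mode is selected (0.1 mm for acrylic IOLs).
#' Defaults reproduce the observed +0.11 mm phakic/aphakic reading excess
#' over the pseudophakic mode.
#'
#' @param phakic,aphakic,pseudophakic Offsets (mm) relative to the
#'   pseudophakic display.
#' @param acrylate_correction Constant (mm) added by the
#'   pseudophakic-acrylate display conversion.
#' @return An object of class `mode_offsets`.
#' @export
mode_offsets <- function(phakic = 0.11, aphakic = 0.11, pseudophakic = 0,
                         acrylate_correction = 0.1) {
  for (v in c(phakic, aphakic, pseudophakic, acrylate_correction)) {
    if (!is.finite(v)) stop("mode offsets must be finite", call. = FALSE)
  }
  structure(list(phakic = phakic, aphakic = aphakic,
                 pseudophakic = pseudophakic,
                 acrylate_correction = acrylate_correction),
            class = "mode_offsets")
}

#' Lens constants for one IOL model
#'
#' Bundles the SRK-family A-constant with its formula-specific
#' counterparts: the Hoffer Q personalized anterior chamber depth (pACD)
#' and the Holladay surgeon factor (SF). `source` records how the values
#' were obtained.
#'
#' @param a_constant A-constant (A-units), in \[110, 125\].
#' @param pacd Predicted ACD (mm), in \[1, 9\]; if `NULL`, derived from the
#'   A-constant via [convert_a_constant()].
#' @param sf Surgeon factor (mm), in \[-2, 6\]; if `NULL`, derived likewise.
#' @param source One of `"catalog"`, `"converted"`, `"optimized"`.
#' @return An object of class `lens_constants`.
#' @export
lens_constants <- function(a_constant, pacd = NULL, sf = NULL,
                           source = "catalog") {
  stopifnot(is.numeric(a_constant), length(a_constant) == 1L)
  if (a_constant < 110 || a_constant > 125) {
    stop("a_constant ", a_constant, " outside [110, 125]", call. = FALSE)
  }
  if (is.null(pacd)) pacd <- 0.58357 * a_constant - 63.896
  if (is.null(sf)) sf <- 0.5663 * a_constant - 65.60
  if (pacd < 1 || pacd > 9) stop("pacd ", pacd, " outside [1, 9]", call. = FALSE)
  if (sf < -2 || sf > 6) stop("sf ", sf, " outside [-2, 6]", call. = FALSE)
  source <- match.arg(source, c("catalog", "converted", "optimized"))
  structure(list(a_constant = a_constant, pacd = pacd, sf = sf,
                 source = source),
            class = "lens_constants")
}

#' @export
print.lens_constants <- function(x, ...) {
  cat(sprintf("Lens constants (%s): A = %.2f, pACD = %.2f mm, SF = %.2f mm\n",
              x$source, x$a_constant, x$pacd, x$sf))
  invisible(x)
}

#' Corneal radius of curvature from keratometric power
#'
#' Standard keratometric relation r = 337.5 / K (keratometric index
#' 1.3375). The formulas' internal corneal indices (1.333 for SRK/T, 4/3
#' for Holladay 1) are separate and applied downstream.
#'
#' @param km Corneal power (D), positive.
#' @return Radius (mm).
#' @export
corneal_radius_from_k <- function(km) {
  if (any(!is.finite(km)) || any(km <= 0)) {
    stop("corneal power must be positive", call. = FALSE)
  }
  337.5 / km
}

#' Keratometric power from corneal radius
#' @param r Radius (mm), positive.
#' @return Power (D).
#' @export
keratometry_from_radius <- function(r) {
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("corneal radius must be positive", call. = FALSE)
  }
  337.5 / r
}

#' Convert a refraction between spectacle and corneal plane
#'
#' Vertex conversion for a refraction of R diopters across a vertex
#' distance V mm: R/(1 - 0.001 V R) towards the cornea and
#' R/(1 + 0.001 V R) back to the spectacle plane; the two directions are
#' mutual inverses.
#'
#' @param refraction Refraction (D); vectorized.
#' @param vertex_mm Vertex distance (mm), default 12.
#' @param direction `"spectacle_to_cornea"` or `"cornea_to_spectacle"`.
#' @return Converted refraction (D).
#' @export
vertex_convert <- function(refraction, vertex_mm = 12,
                           direction = c("spectacle_to_cornea",
                                         "cornea_to_spectacle")) {
  direction <- match.arg(direction)
  s <- if (direction == "spectacle_to_cornea") -1 else 1
  den <- 1 + s * 0.001 * vertex_mm * refraction
  if (any(abs(den) < 1e-12)) {
    stop("vertex conversion singular at this refraction", call. = FALSE)
  }
  refraction / den
}

#' Displayed axial length under a measurement mode
#'
#' Applies the additive instrument model to a raw optical AL: the
#' pseudophakic-acrylate mode displays raw + `acrylate_correction`; the
#' other modes display raw + (mode offset - pseudophakic offset +
#' `acrylate_correction`), so pairwise displayed differences equal the
#' configured relative offsets regardless of the raw value.
#'
#' @param raw_optical_al Raw optical AL (mm), within the plausible range.
#' @param mode One of `"Ph"`, `"Ap"`, `"Ps"`.
#' @param offsets A [mode_offsets()] object.
#' @return Displayed AL (mm).
#' @export
display_al <- function(raw_optical_al, mode, offsets = mode_offsets()) {
  .check_al_option(mode)
  stopifnot(inherits(offsets, "mode_offsets"))
  if (any(raw_optical_al < .AL_RANGE[1]) || any(raw_optical_al > .AL_RANGE[2])) {
    stop("raw optical AL outside the plausible range [",
         .AL_RANGE[1], ", ", .AL_RANGE[2], "] mm", call. = FALSE)
  }
  rel <- switch(mode,
                Ph = offsets$phakic - offsets$pseudophakic,
                Ap = offsets$aphakic - offsets$pseudophakic,
                Ps = 0)
  raw_optical_al + rel + offsets$acrylate_correction
}

# Column schema of the cohort table (one row per eye).
.COHORT_COLUMNS <- c("patient_id", "eye_role", "al_pre_phakic",
                     "al_post_aphakic", "al_post_pseudophakic",
                     "al_post_repeat", "km_pre", "km_post", "iol_model",
                     "iol_a_constant", "iol_power", "postop_se",
                     "has_stable_refraction")

.in_range <- function(x, range) is.na(x) | (x >= range[1] & x <= range[2])

#' Validate a cohort table
#'
#' Checks the cohort data.frame (one row per eye) against the schema:
#' required columns, AL values within \[15, 40\] mm, keratometry within
#' \[30, 60\] D, IOL power within \[-10, 40\] D, `eye_role` in
#' \{operated, fellow\}, and `postop_se` present only where
#' `has_stable_refraction` is TRUE. Errors name the offending row and
#' column.
#'
#' @param cohort A data.frame with the cohort columns.
#' @return The cohort, invisibly, if valid.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(.COHORT_COLUMNS, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(names(cohort), .COHORT_COLUMNS)
  if (length(unknown)) {
    stop("unknown cohort columns: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  bad_role <- which(!cohort$eye_role %in% c("operated", "fellow"))
  if (length(bad_role)) {
    stop("row ", bad_role[1], ": eye_role must be 'operated' or 'fellow'",
         call. = FALSE)
  }
  for (col in c("al_pre_phakic", "al_post_aphakic", "al_post_pseudophakic",
                "al_post_repeat")) {
    bad <- which(!.in_range(cohort[[col]], .AL_RANGE))
    if (length(bad)) {
      stop("row ", bad[1], ", column ", col, ": AL ", cohort[[col]][bad[1]],
           " outside [", .AL_RANGE[1], ", ", .AL_RANGE[2], "] mm",
           call. = FALSE)
    }
  }
  for (col in c("km_pre", "km_post")) {
    bad <- which(!.in_range(cohort[[col]], .KM_RANGE))
    if (length(bad)) {
      stop("row ", bad[1], ", column ", col, ": keratometry ",
           cohort[[col]][bad[1]], " outside [", .KM_RANGE[1], ", ",
           .KM_RANGE[2], "] D", call. = FALSE)
    }
  }
  bad <- which(!.in_range(cohort$iol_power, .POWER_RANGE))
  if (length(bad)) {
    stop("row ", bad[1], ", column iol_power: ", cohort$iol_power[bad[1]],
         " outside [", .POWER_RANGE[1], ", ", .POWER_RANGE[2], "] D",
         call. = FALSE)
  }
  bad <- which(!is.na(cohort$postop_se) & !cohort$has_stable_refraction)
  if (length(bad)) {
    stop("row ", bad[1], ": postop_se present without a stable refraction",
         call. = FALSE)
  }
  invisible(cohort)
}
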