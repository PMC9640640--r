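# Thin-lens vergence IOL power formulas: SRK/T, Hoffer Q, Holladay 1 and
# the AL-switched Combo method. Each formula predicts the postoperative
# spherical-equivalent refraction at the spectacle plane (vertex 12 mm by
# default) for a given axial length, mean keratometry, lens constant and
# implanted IOL power, and can solve for the emmetropic power.

.VERTEX_DEFAULT <- 12   # mm, spectacle plane
.NA_AQUEOUS <- 1.336    # aqueous/vitreous refractive index in the vergence step

.check_prediction_input <- function(al, km, iol_power = 0) {
  if (!is.finite(al) || al < .AL_RANGE[1] || al > .AL_RANGE[2]) {
    stop("axial length ", al, " outside [", .AL_RANGE[1], ", ",
         .AL_RANGE[2], "] mm", call. = FALSE)
  }
  if (!is.finite(km) || km < .KM_RANGE[1] || km > .KM_RANGE[2]) {
    stop("keratometry ", km, " outside [", .KM_RANGE[1], ", ",
         .KM_RANGE[2], "] D", call. = FALSE)
  }
  if (!is.finite(iol_power)) stop("IOL power must be finite", call. = FALSE)
  invisible(NULL)
}

# Generalized back-calculated refraction shared by SRK/T and Holladay 1:
# cornea as a thin lens of power 1000*ncm1/r at the corneal plane, IOL of
# power p at the ELP, image plane at the optical AL, solved for the
# spectacle-plane refraction.
.vergence_refraction <- function(r, lopt, elp, p, ncm1,
                                 na = .NA_AQUEOUS, v = .VERTEX_DEFAULT) {
  num <- 1000 * na * (na * r - ncm1 * lopt) -
    p * (lopt - elp) * (na * r - ncm1 * elp)
  den <- na * (v * (na * r - ncm1 * lopt) + lopt * r) -
    0.001 * p * (lopt - elp) * (v * (na * r - ncm1 * elp) + elp * r)
  if (abs(den) < 1e-12) stop("degenerate vergence denominator", call. = FALSE)
  num / den
}

.vergence_emmetropia_power <- function(r, lopt, elp, ncm1, na = .NA_AQUEOUS) {
  den <- (lopt - elp) * (na * r - ncm1 * elp)
  if (abs(den) < 1e-12) stop("degenerate emmetropia denominator", call. = FALSE)
  1000 * na * (na * r - ncm1 * lopt) / den
}

#' SRK/T formula intermediates
#'
#' Computes the published SRK/T chain: corneal radius, corrected AL
#' (LCOR, quadratic above 24.2 mm), computed corneal width (Cw), corneal
#' dome height (H), the A-constant-derived ACD constant and offset, the
#' ELP estimate (ACDest), retinal thickness and optical AL.
#'
#' @param al Axial length (mm).
#' @param km Mean keratometry (D).
#' @param constants A [lens_constants()] object (the A-constant is used).
#' @return List of named intermediates.
#' @export
srkt_intermediates <- function(al, km, constants) {
  .check_prediction_input(al, km)
  stopifnot(inherits(constants, "lens_constants"))
  r <- corneal_radius_from_k(km)
  lcor <- if (al <= 24.2) al else -3.446 + 1.716 * al - 0.0237 * al^2
  cw <- -5.41 + 0.58412 * lcor + 0.098 * km
  disc <- r^2 - cw^2 / 4
  if (disc < 0) {
    warning("SRK/T corneal height guard triggered (steep cornea): ",
            "r^2 < Cw^2/4; clamping to 0", call. = FALSE)
    disc <- 0
  }
  h <- r - sqrt(disc)
  acd_const <- 0.62467 * constants$a_constant - 68.747
  offset <- acd_const - 3.336
  acd_est <- h + offset
  rethick <- 0.65696 - 0.02029 * al
  list(r = r, lcor = lcor, cw = cw, h = h, acd_const = acd_const,
       offset = offset, acd_est = acd_est, rethick = rethick,
       lopt = al + rethick, na = .NA_AQUEOUS, ncm1 = 0.333,
       v = .VERTEX_DEFAULT)
}

#' SRK/T predicted refraction
#'
#' Back-calculated postoperative spherical-equivalent refraction at the
#' spectacle plane for an implanted power, using the SRK/T ELP estimate
#' and internal corneal index 1.333.
#'
#' @inheritParams srkt_intermediates
#' @param iol_power Implanted IOL power (D).
#' @return Predicted refraction (D, spectacle plane).
#' @export
srkt_predicted_refraction <- function(al, km, constants, iol_power) {
  .check_prediction_input(al, km, iol_power)
  z <- srkt_intermediates(al, km, constants)
  .vergence_refraction(z$r, z$lopt, z$acd_est, iol_power, z$ncm1, z$na, z$v)
}

#' SRK/T emmetropic IOL power
#' @inheritParams srkt_intermediates
#' @return Power (D) giving zero predicted refraction.
#' @export
srkt_emmetropia_power <- function(al, km, constants) {
  z <- srkt_intermediates(al, km, constants)
  .vergence_emmetropia_power(z$r, z$lopt, z$acd_est, z$ncm1, z$na)
}

#' Hoffer Q formula intermediates
#'
#' Personalized-ACD chain with the published AL clamp to \[18.5, 31\] mm
#' and the short/long-eye branch (M = +1, G = 28 for clamped AL <= 23 mm,
#' else M = -1, G = 23.5). Trigonometric arguments are in degrees.
#'
#' @param al Axial length (mm).
#' @param km Mean keratometry (D).
#' @param constants A [lens_constants()] object (pACD is used).
#' @return List with `alm`, `m`, `g`, `acd_pred`.
#' @export
hofferq_intermediates <- function(al, km, constants) {
  .check_prediction_input(al, km)
  stopifnot(inherits(constants, "lens_constants"))
  alm <- min(max(al, 18.5), 31)
  if (alm <= 23) { m <- 1; g <- 28 } else { m <- -1; g <- 23.5 }
  deg <- pi / 180
  acd_pred <- constants$pacd + 0.3 * (alm - 23.5) + tan(km * deg)^2 +
    0.1 * m * (23.5 - alm)^2 * tan(0.1 * (g - alm)^2 * deg) - 0.99166
  list(alm = alm, m = m, g = g, acd_pred = acd_pred)
}

#' Hoffer Q predicted refraction
#'
#' Solves the Hoffer Q power equation for the corneal-plane refraction in
#' closed form, then converts to the spectacle plane across the vertex
#' distance. The cornea enters at its keratometric power; the ELP is the
#' personalized ACD plus the 0.05 mm retina-offset term.
#'
#' @inheritParams hofferq_intermediates
#' @param iol_power Implanted IOL power (D).
#' @param vertex_mm Vertex distance (mm) for the spectacle conversion.
#' @return Predicted refraction (D, spectacle plane).
#' @export
hofferq_predicted_refraction <- function(al, km, constants, iol_power,
                                         vertex_mm = .VERTEX_DEFAULT) {
  .check_prediction_input(al, km, iol_power)
  z <- hofferq_intermediates(al, km, constants)
  x <- al - z$acd_pred - 0.05
  if (x <= 0) stop("Hoffer Q: AL - ACD - 0.05 not positive", call. = FALSE)
  a1 <- 1336 / x - iol_power
  if (abs(a1) < 1e-12) stop("Hoffer Q: singular vergence at IOL", call. = FALSE)
  a2 <- 1.336 / a1 + (z$acd_pred + 0.05) / 1000
  if (abs(a2) < 1e-12) stop("Hoffer Q: singular corneal vergence", call. = FALSE)
  rc <- 1.336 / a2 - km
  vertex_convert(rc, vertex_mm, "cornea_to_spectacle")
}

#' Hoffer Q emmetropic IOL power
#' @inheritParams hofferq_intermediates
#' @return Power (D) giving zero refraction.
#' @export
hofferq_emmetropia_power <- function(al, km, constants) {
  z <- hofferq_intermediates(al, km, constants)
  x <- al - z$acd_pred - 0.05
  if (x <= 0) stop("Hoffer Q: AL - ACD - 0.05 not positive", call. = FALSE)
  1336 / x - 1.336 / (1.336 / km - (z$acd_pred + 0.05) / 1000)
}

#' Holladay 1 formula intermediates
#'
#' Anatomical ACD from corneal geometry (radius floored at 7 mm, chord
#' capped at 13.5 mm) plus the surgeon factor; internal corneal index 4/3
#' and a fixed +0.2 mm AL extension.
#'
#' @param al Axial length (mm).
#' @param km Mean keratometry (D).
#' @param constants A [lens_constants()] object (SF is used).
#' @return List with `rag`, `ag`, `acd_anat`, `elp`, `alm`.
#' @export
holladay1_intermediates <- function(al, km, constants) {
  .check_prediction_input(al, km)
  stopifnot(inherits(constants, "lens_constants"))
  r <- corneal_radius_from_k(km)
  rag <- max(r, 7)
  ag <- min(12.5 * al / 23.45, 13.5)
  disc <- rag^2 - ag^2 / 4
  if (disc < 0) {
    stop("Holladay 1: corneal geometry degenerate (Rag^2 < AG^2/4)",
         call. = FALSE)
  }
  acd_anat <- 0.56 + rag - sqrt(disc)
  list(r = r, rag = rag, ag = ag, acd_anat = acd_anat,
       elp = acd_anat + constants$sf, alm = al + 0.2,
       na = .NA_AQUEOUS, ncm1 = 1 / 3, v = .VERTEX_DEFAULT)
}

#' Holladay 1 predicted refraction
#' @inheritParams holladay1_intermediates
#' @param iol_power Implanted IOL power (D).
#' @return Predicted refraction (D, spectacle plane).
#' @export
holladay1_predicted_refraction <- function(al, km, constants, iol_power) {
  .check_prediction_input(al, km, iol_power)
  z <- holladay1_intermediates(al, km, constants)
  .vergence_refraction(z$r, z$alm, z$elp, iol_power, z$ncm1, z$na, z$v)
}

#' Holladay 1 emmetropic IOL power
#' @inheritParams holladay1_intermediates
#' @return Power (D) giving zero refraction.
#' @export
holladay1_emmetropia_power <- function(al, km, constants) {
  z <- holladay1_intermediates(al, km, constants)
  .vergence_emmetropia_power(z$r, z$alm, z$elp, z$ncm1, z$na)
}

#' Formula identifiers
#' @return Character vector `c("srkt", "hofferq", "holladay1", "combo")`.
#' @export
formula_ids <- function() c("srkt", "hofferq", "holladay1", "combo")

#' Combo (AL-switched) predicted refraction
#'
#' Dispatches on the AL reading used for the prediction: Hoffer Q below
#' 23.00 mm, SRK/T at or above 23.00 mm. Both the pACD and the A-constant
#' must be available in `constants`.
#'
#' @inheritParams srkt_intermediates
#' @param iol_power Implanted IOL power (D).
#' @return Predicted refraction (D, spectacle plane).
#' @export
combo_predicted_refraction <- function(al, km, constants, iol_power) {
  if (al < 23) {
    hofferq_predicted_refraction(al, km, constants, iol_power)
  } else {
    srkt_predicted_refraction(al, km, constants, iol_power)
  }
}

#' Predicted refraction under a named formula
#'
#' @param formula One of [formula_ids()].
#' @inheritParams srkt_intermediates
#' @param iol_power Implanted IOL power (D).
#' @return Predicted refraction (D, spectacle plane).
#' @export
predict_refraction <- function(formula, al, km, constants, iol_power) {
  formula <- match.arg(formula, formula_ids())
  switch(formula,
         srkt = srkt_predicted_refraction(al, km, constants, iol_power),
         hofferq = hofferq_predicted_refraction(al, km, constants, iol_power),
         holladay1 = holladay1_predicted_refraction(al, km, constants,
                                                    iol_power),
         combo = combo_predicted_refraction(al, km, constants, iol_power))
}

#' Emmetropic power under a named formula
#' @inheritParams predict_refraction
#' @return Power (D) giving zero predicted refraction.
#' @export
emmetropia_power <- function(formula, al, km, constants) {
  formula <- match.arg(formula, formula_ids())
  switch(formula,
         srkt = srkt_emmetropia_power(al, km, constants),
         hofferq = hofferq_emmetropia_power(al, km, constants),
         holladay1 = holladay1_emmetropia_power(al, km, constants),
         combo = if (al < 23) hofferq_emmetropia_power(al, km, constants)
                 else srkt_emmetropia_power(al, km, constants))
}

#' IOL power achieving a target refraction
#'
#' Solves for the power whose predicted refraction equals `target` (D,
#' spectacle plane) by bracketed root finding; predicted refraction is
#' strictly decreasing in power, so the root is unique.
#'
#' @inheritParams predict_refraction
#' @param target Target refraction (D), default plano.
#' @return Power (D).
#' @export
power_for_target <- function(formula, al, km, constants, target = 0) {
  f <- function(p) predict_refraction(formula, al, km, constants, p) - target
  stats::uniroot(f, interval = .POWER_RANGE, tol = 1e-10,
                 extendInt = "downX")$root
}

#' Convert an A-constant to Hoffer Q and Holladay constants
#'
#' Standard linear conversions: SF = 0.5663 A - 65.60 and
#' pACD = 0.58357 A - 63.896.
#'
#' @param a A-constant (A-units).
#' @return A [lens_constants()] object with `source = "converted"`.
#' @export
convert_a_constant <- function(a) {
  lens_constants(a_constant = a,
                 pacd = 0.58357 * a - 63.896,
                 sf = 0.5663 * a - 65.60,
                 source = "converted")
}
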