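# Synthetic biometry cohorts with the statistical structure the analysis
# assumes: per-patient operated + fellow eyes, per-mode AL readings with
# a systematic phakic/aphakic excess over the pseudophakic display,
# formula-consistent IOL powers and postoperative refractions carrying a
# constant bias that emulates un-optimized catalog lens constants.

#' Parameters of the synthetic cohort generator
#'
#' Defaults reproduce the study conditions of a 201-patient cataract
#' cohort measured on a PCI biometer: AL ~ 23.59 (1.35) mm truncated to
#' the observed range, Km ~ 43.98 (1.56) D, a +0.11 mm phakic/aphakic
#' reading excess over the pseudophakic display with 0.07 mm paired
#' noise, 0.05 mm fellow-eye repeatability noise, keratometry change SDs
#' of 0.39/0.36 D (operated/fellow), stable refraction in 133/201 of
#' patients, IOL powers chosen for a -0.25 D target and rounded to 0.5 D,
#' 0.35 D refraction noise, and a +0.25 D constant-bias term.
#'
#' @param n_patients Number of patients (one operated + one fellow eye).
#' @param stable_refraction_fraction Probability an operated eye reaches
#'   a stable postoperative refraction.
#' @param al_mean,al_sd True-AL population mean and SD (mm).
#' @param al_bounds Truncation bounds (mm) for the true AL.
#' @param km_mean,km_sd Keratometry population mean and SD (D).
#' @param km_bounds Truncation bounds (D) for the keratometry draw,
#'   matching the observed preoperative range.
#' @param offsets A [mode_offsets()] object for the instrument model.
#' @param paired_noise_sd SD (mm) of the phakic/aphakic reading noise.
#' @param fellow_noise_sd SD (mm) of the fellow-eye repeat reading noise.
#' @param km_noise_sd_operated,km_noise_sd_fellow SD (D) of the pre/post
#'   keratometry change.
#' @param true_formula Formula generating powers and refractions.
#' @param true_constants [lens_constants()] used by the generating
#'   formula.
#' @param target_refraction Surgeon's refractive target (D).
#' @param power_step IOL power rounding step (D).
#' @param refraction_noise_sd SD (D) of the postoperative refraction.
#' @param constant_bias_d Constant refraction offset (D) emulating
#'   un-optimized catalog constants.
#' @param iol_model IOL model label written to the cohort.
#' @return An object of class `generator_params`.
#' @export
generator_params <- function(n_patients = 201,
                             stable_refraction_fraction = 133 / 201,
                             al_mean = 23.59, al_sd = 1.35,
                             al_bounds = c(20.3, 32.2),
                             km_mean = 43.98, km_sd = 1.56,
                             km_bounds = c(40.1, 48.1),
                             offsets = mode_offsets(),
                             paired_noise_sd = 0.07,
                             fellow_noise_sd = 0.05,
                             km_noise_sd_operated = 0.39,
                             km_noise_sd_fellow = 0.36,
                             true_formula = "srkt",
                             true_constants = lens_constants(119.30),
                             target_refraction = -0.25,
                             power_step = 0.5,
                             refraction_noise_sd = 0.35,
                             constant_bias_d = 0.25,
                             iol_model = "Tecnis PCB00") {
  sds <- c(al_sd, km_sd, paired_noise_sd, fellow_noise_sd,
           km_noise_sd_operated, km_noise_sd_fellow, refraction_noise_sd)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("all noise SDs must be finite and non-negative", call. = FALSE)
  }
  if (stable_refraction_fraction < 0 || stable_refraction_fraction > 1) {
    stop("stable_refraction_fraction outside [0, 1]", call. = FALSE)
  }
  if (n_patients < 1) stop("n_patients must be positive", call. = FALSE)
  if (al_mean < .AL_RANGE[1] || al_mean > .AL_RANGE[2] ||
      km_mean < .KM_RANGE[1] || km_mean > .KM_RANGE[2]) {
    stop("population means outside plausible biometry ranges", call. = FALSE)
  }
  if (al_bounds[1] >= al_bounds[2] || km_bounds[1] >= km_bounds[2]) {
    stop("invalid truncation bounds", call. = FALSE)
  }
  if (power_step <= 0) stop("power_step must be positive", call. = FALSE)
  true_formula <- match.arg(true_formula, formula_ids())
  stopifnot(inherits(offsets, "mode_offsets"),
            inherits(true_constants, "lens_constants"))
  structure(as.list(environment())[c(
    "n_patients", "stable_refraction_fraction", "al_mean", "al_sd",
    "al_bounds", "km_mean", "km_sd", "km_bounds", "offsets", "paired_noise_sd",
    "fellow_noise_sd", "km_noise_sd_operated", "km_noise_sd_fellow",
    "true_formula", "true_constants", "target_refraction", "power_step",
    "refraction_noise_sd", "constant_bias_d", "iol_model")],
    class = "generator_params")
}

# truncated-normal draw by rejection; vectorized over n
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Generate a synthetic biometry cohort
#'
#' Produces one operated and one fellow eye per patient. The displayed
#' pseudophakic-option reading anchors the operated eye at its true AL;
#' the phakic and aphakic readings sit above it by the configured
#' instrument offsets plus paired noise, so the cohort reproduces the
#' phakic-mode systematic error the analysis is designed to detect. The
#' implanted power is the formula's power for the refractive target
#' (phakic AL, rounded to the power step) and the achieved refraction is
#' the formula's prediction from the pseudophakic AL plus the constant
#' bias and refraction noise.
#'
#' @param params A [generator_params()] object.
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @return A validated cohort data.frame, one row per eye
#'   (2 * n_patients rows).
#' @export
generate_cohort <- function(params = generator_params(), seed = 1) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(as.integer(seed))
  n <- params$n_patients
  off <- params$offsets
  rel_ph <- off$phakic - off$pseudophakic
  rel_ap <- off$aphakic - off$pseudophakic

  make_eye <- function(role, idx) {
    true_al <- .rtruncnorm(n, params$al_mean, params$al_sd,
                           params$al_bounds[1], params$al_bounds[2])
    km_pre <- .rtruncnorm(n, params$km_mean, params$km_sd,
                          params$km_bounds[1], params$km_bounds[2])
    if (role == "operated") {
      al_ps <- true_al + off$pseudophakic
      al_ph <- al_ps + rel_ph + stats::rnorm(n, 0, params$paired_noise_sd)
      al_ap <- al_ph + stats::rnorm(n, 0, params$paired_noise_sd) -
        (rel_ph - rel_ap)
      km_post <- km_pre + stats::rnorm(n, 0, params$km_noise_sd_operated)
      power <- vapply(seq_len(n), function(i) {
        p <- power_for_target(params$true_formula, al_ph[i], km_pre[i],
                              params$true_constants,
                              params$target_refraction)
        round(p / params$power_step) * params$power_step
      }, numeric(1))
      stable <- stats::runif(n) < params$stable_refraction_fraction
      se <- vapply(seq_len(n), function(i) {
        predict_refraction(params$true_formula, al_ps[i], km_pre[i],
                           params$true_constants, power[i]) +
          params$constant_bias_d
      }, numeric(1)) + stats::rnorm(n, 0, params$refraction_noise_sd)
      se[!stable] <- NA_real_
      data.frame(patient_id = sprintf("P%04d", idx), eye_role = role,
                 al_pre_phakic = al_ph, al_post_aphakic = al_ap,
                 al_post_pseudophakic = al_ps, al_post_repeat = NA_real_,
                 km_pre = km_pre, km_post = km_post,
                 iol_model = params$iol_model,
                 iol_a_constant = params$true_constants$a_constant,
                 iol_power = power, postop_se = se,
                 has_stable_refraction = stable, stringsAsFactors = FALSE)
    } else {
      al_ph <- true_al + rel_ph + off$pseudophakic
      al_rep <- al_ph + stats::rnorm(n, 0, params$fellow_noise_sd)
      km_post <- km_pre + stats::rnorm(n, 0, params$km_noise_sd_fellow)
      data.frame(patient_id = sprintf("P%04d", idx), eye_role = role,
                 al_pre_phakic = al_ph, al_post_aphakic = NA_real_,
                 al_post_pseudophakic = NA_real_, al_post_repeat = al_rep,
                 km_pre = km_pre, km_post = km_post,
                 iol_model = params$iol_model,
                 iol_a_constant = params$true_constants$a_constant,
                 iol_power = NA_real_, postop_se = NA_real_,
                 has_stable_refraction = FALSE, stringsAsFactors = FALSE)
    }
  }

  idx <- seq_len(n)
  cohort <- rbind(make_eye("operated", idx), make_eye("fellow", idx))
  cohort <- cohort[order(cohort$patient_id, cohort$eye_role), ]
  rownames(cohort) <- NULL
  validate_cohort(cohort)
  cohort
}

#' Population-level expectations implied by generator parameters
#'
#' Closed-form expectations of the paired summaries the analysis
#' computes, for use in tests and documentation: the mean displayed
#' differences between modes equal the configured relative offsets and
#' their SDs equal the configured noise SDs.
#'
#' @param params A [generator_params()] object.
#' @return A data.frame of expected paired differences (mean, sd).
#' @export
expected_cohort_summaries <- function(params = generator_params()) {
  off <- params$offsets
  rel_ph <- off$phakic - off$pseudophakic
  rel_ap <- off$aphakic - off$pseudophakic
  data.frame(
    comparison = c("al_post_pseudophakic - al_pre_phakic",
                   "al_post_aphakic - al_pre_phakic",
                   "al_post_repeat - al_pre_phakic (fellow)",
                   "km_post - km_pre (operated)",
                   "km_post - km_pre (fellow)"),
    mean = c(-rel_ph, rel_ap - rel_ph, 0, 0, 0),
    sd = c(params$paired_noise_sd, params$paired_noise_sd,
           params$fellow_noise_sd, params$km_noise_sd_operated,
           params$km_noise_sd_fellow),
    stringsAsFactors = FALSE)
}
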