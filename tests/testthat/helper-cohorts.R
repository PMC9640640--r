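# Cohort fixtures built in code.

# Noise-free cohort generated self-consistently from a formula: the
# achieved refraction equals the formula's own prediction from the
# pseudophakic reading, so prediction errors vanish by construction.
noise_free_params <- function(n = 25, formula = "srkt",
                              constants = lens_constants(119.30),
                              bias = 0) {
  generator_params(n_patients = n, stable_refraction_fraction = 1,
                   paired_noise_sd = 0, fellow_noise_sd = 0,
                   km_noise_sd_operated = 0, km_noise_sd_fellow = 0,
                   refraction_noise_sd = 0, constant_bias_d = bias,
                   true_formula = formula, true_constants = constants)
}

default_cohort <- function(seed = 1, ...) {
  suppressWarnings(generate_cohort(generator_params(...), seed = seed))
}

operated <- function(cohort) cohort[cohort$eye_role == "operated", ]
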