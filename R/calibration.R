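# Prediction-error back-calculation, lens-constant optimization by
# mean-error zeroing, and the ALc axial-length correction regression.

.al_column_for_option <- function(option) {
  switch(.check_al_option(option),
         Ph = "al_pre_phakic",
         Ap = "al_post_aphakic",
         Ps = "al_post_pseudophakic")
}

#' Refractive prediction error for one eye
#'
#' PE = achieved postoperative spherical-equivalent refraction minus the
#' refraction predicted retrospectively with the implanted power, the AL
#' reading of the requested measurement option, and the preoperative
#' keratometry (keratometry change after surgery is not significant, so
#' the preoperative reading is always used).
#'
#' @param record One cohort row (data.frame or list) with a stable
#'   postoperative refraction.
#' @param formula One of [formula_ids()].
#' @param constants A [lens_constants()] object.
#' @param al_option `"Ph"`, `"Ap"` or `"Ps"` — which AL reading to use.
#' @return Prediction error (D).
#' @export
prediction_error <- function(record, formula, constants, al_option) {
  if (!isTRUE(as.logical(record$has_stable_refraction)) ||
      is.na(record$postop_se)) {
    stop("prediction error requires a stable postoperative refraction",
         call. = FALSE)
  }
  col <- .al_column_for_option(al_option)
  al <- record[[col]]
  if (is.null(al) || is.na(al)) {
    stop("AL reading for option '", al_option, "' (", col, ") is missing",
         call. = FALSE)
  }
  record$postop_se -
    predict_refraction(formula, al, record$km_pre, constants,
                       record$iol_power)
}

# Vectorized over the eligible rows of a cohort.
.prediction_errors <- function(cohort, formula, constants, al_option) {
  col <- .al_column_for_option(al_option)
  rows <- which(cohort$eye_role == "operated" &
                  cohort$has_stable_refraction %in% TRUE &
                  !is.na(cohort$postop_se))
  if (!length(rows)) stop("no eligible eyes with a stable refraction",
                          call. = FALSE)
  miss <- rows[is.na(cohort[[col]][rows])]
  if (length(miss)) {
    stop("AL reading for option '", al_option, "' missing in row ", miss[1],
         call. = FALSE)
  }
  vapply(rows, function(i) {
    cohort$postop_se[i] -
      predict_refraction(formula, cohort[[col]][i], cohort$km_pre[i],
                         constants, cohort$iol_power[i])
  }, numeric(1))
}

#' Summary statistics of a prediction-error vector
#'
#' @param pe Numeric vector of prediction errors (D), length >= 2.
#' @return List with `me` (mean error), `sd` (sample SD, n-1), `medae`
#'   (median absolute error) and `n`.
#' @export
summarize_pe <- function(pe) {
  if (length(pe) < 2) stop("need at least 2 prediction errors", call. = FALSE)
  list(me = mean(pe), sd = stats::sd(pe),
       medae = stats::median(abs(pe)), n = length(pe))
}

#' Optimize a lens constant by zeroing the mean error
#'
#' Finds the constant that drives the cohort mean prediction error to
#' zero, the spreadsheet "goal seek" step of retrospective formula
#' studies, by bracketed root finding (ME is strictly monotone in the
#' constant). The variable is the A-constant for SRK/T and Combo (Combo's
#' pACD is tied through [convert_a_constant()]), the pACD for Hoffer Q,
#' and the surgeon factor for Holladay 1.
#'
#' @param cohort Cohort data.frame.
#' @param formula One of [formula_ids()].
#' @param constants Starting [lens_constants()].
#' @param al_option AL measurement option for the back-calculation.
#' @param bracket Half-width of the search bracket around the starting
#'   constant: A-units for A-constant formulas, mm for pACD/SF.
#' @param tol Mean-error tolerance (D) at the solution.
#' @return Optimized [lens_constants()] with `source = "optimized"`.
#' @export
zero_me_constant <- function(cohort, formula, constants, al_option,
                             bracket = NULL, tol = 1e-4) {
  formula <- match.arg(formula, formula_ids())
  stopifnot(inherits(constants, "lens_constants"))
  uses_a <- formula %in% c("srkt", "combo")
  if (is.null(bracket)) bracket <- if (uses_a) 3 else 1.5
  start <- switch(formula, srkt = , combo = constants$a_constant,
                  hofferq = constants$pacd, holladay1 = constants$sf)
  with_c <- function(c) {
    switch(formula,
           srkt = lens_constants(c, constants$pacd, constants$sf, "optimized"),
           combo = {
             z <- convert_a_constant(c)
             lens_constants(c, z$pacd, z$sf, "optimized")
           },
           hofferq = lens_constants(constants$a_constant, c, constants$sf,
                                    "optimized"),
           holladay1 = lens_constants(constants$a_constant, constants$pacd,
                                      c, "optimized"))
  }
  me_at <- function(c) mean(.prediction_errors(cohort, formula, with_c(c),
                                               al_option))
  lo <- start - bracket; hi <- start + bracket
  f_lo <- me_at(lo); f_hi <- me_at(hi)
  if (sign(f_lo) == sign(f_hi)) {
    stop(sprintf(
      "no mean-error sign change in bracket [%g, %g]: ME(lo) = %.4f, ME(hi) = %.4f",
      lo, hi, f_lo, f_hi), call. = FALSE)
  }
  root <- stats::uniroot(me_at, lower = lo, upper = hi,
                         f.lower = f_lo, f.upper = f_hi, tol = 1e-8)$root
  # polish until |ME| < tol (uniroot's tol is on the argument)
  if (abs(me_at(root)) >= tol) {
    root <- stats::uniroot(me_at, lower = root - 0.01, upper = root + 0.01,
                           extendInt = "yes", tol = 1e-12)$root
  }
  with_c(root)
}

#' Fit the axial-length correction regression
#'
#' Ordinary least squares of the postoperative pseudophakic-option AL on
#' the preoperative phakic-option AL. The fitted line converts a
#' preoperative reading into the AL the biometer would display after
#' surgery, removing the instrument's systematic phakic-mode error.
#'
#' @param al_pre Preoperative phakic-option AL readings (mm).
#' @param al_post_ps Paired postoperative pseudophakic-option readings (mm).
#' @return An object of class `al_correction` with `intercept` (mm),
#'   `slope` and `r_squared`.
#' @export
fit_al_correction <- function(al_pre, al_post_ps) {
  if (length(al_pre) != length(al_post_ps)) {
    stop("paired AL vectors must have equal length", call. = FALSE)
  }
  keep <- stats::complete.cases(al_pre, al_post_ps)
  al_pre <- al_pre[keep]; al_post_ps <- al_post_ps[keep]
  if (length(al_pre) < 3) stop("need at least 3 paired readings", call. = FALSE)
  if (stats::var(al_pre) == 0) {
    stop("preoperative AL has zero variance; regression undefined",
         call. = FALSE)
  }
  fit <- stats::lm(al_post_ps ~ al_pre)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((al_post_ps - mean(al_post_ps))^2)
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 n = length(al_pre)),
            class = "al_correction")
}

#' Construct an AL correction from known coefficients
#' @param intercept Intercept (mm).
#' @param slope Slope (dimensionless).
#' @param r_squared Optional R-squared in \[0, 1\].
#' @return An `al_correction` object.
#' @export
al_correction <- function(intercept, slope, r_squared = NA_real_) {
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1)) {
    stop("r_squared outside [0, 1]", call. = FALSE)
  }
  structure(list(intercept = intercept, slope = slope,
                 r_squared = r_squared, n = NA_integer_),
            class = "al_correction")
}

#' @export
print.al_correction <- function(x, ...) {
  cat(sprintf("ALc = %.3f + %.3f * AL  (R^2 = %s)\n", x$intercept, x$slope,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared))))
  invisible(x)
}

#' Apply an axial-length correction
#'
#' ALc = intercept + slope * AL.
#'
#' @param al AL reading(s) (mm).
#' @param corr An `al_correction` object.
#' @return Corrected AL (mm).
#' @export
apply_al_correction <- function(al, corr) {
  stopifnot(inherits(corr, "al_correction"))
  corr$intercept + corr$slope * al
}

#' Evaluate formulas across AL measurement options
#'
#' For every requested formula and AL option, computes the
#' prediction-error summary with the supplied constants and, optionally,
#' after zeroing the mean error by constant optimization. Rows are
#' ordered by formula then option.
#'
#' @param cohort Cohort data.frame.
#' @param formulas Character vector from [formula_ids()].
#' @param constants Starting [lens_constants()] shared by all formulas.
#' @param options AL options to evaluate.
#' @param optimize Also compute optimized-constant summaries?
#' @return A data.frame with one row per formula x option: `me`, `sd`,
#'   `medae`, `n` under the supplied constants; when `optimize = TRUE`,
#'   also the optimized constant value and `me_opt`, `sd_opt`,
#'   `medae_opt`.
#' @export
evaluate_options <- function(cohort, formulas = formula_ids(),
                             constants = lens_constants(119.30),
                             options = al_options(), optimize = TRUE) {
  formulas <- match.arg(formulas, formula_ids(), several.ok = TRUE)
  for (o in options) .check_al_option(o)
  rows <- list()
  for (f in formulas) {
    for (o in options) {
      pe <- .prediction_errors(cohort, f, constants, o)
      s <- summarize_pe(pe)
      row <- data.frame(formula = f, al_option = o, n = s$n,
                        me = s$me, sd = s$sd, medae = s$medae,
                        stringsAsFactors = FALSE)
      if (optimize) {
        opt <- zero_me_constant(cohort, f, constants, o)
        pe_opt <- .prediction_errors(cohort, f, opt, o)
        s2 <- summarize_pe(pe_opt)
        row$optimized_constant <- switch(f, srkt = , combo = opt$a_constant,
                                         hofferq = opt$pacd,
                                         holladay1 = opt$sf)
        row$me_opt <- s2$me; row$sd_opt <- s2$sd; row$medae_opt <- s2$medae
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
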