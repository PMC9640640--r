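# Cohort CSV reading/writing and the end-to-end study pipeline.

#' Read a cohort table from CSV
#'
#' Expects the schema written by [write_cohort()]: one row per eye,
#' header mandatory, decimal point ".", empty cells for missing values.
#' The table is validated on read; errors name the offending row and
#' column.
#'
#' @param path Path to the CSV file.
#' @return A validated cohort data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = c(patient_id = "character",
                                           eye_role = "character",
                                           iol_model = "character"))
  num_cols <- c("al_pre_phakic", "al_post_aphakic", "al_post_pseudophakic",
                "al_post_repeat", "km_pre", "km_post", "iol_a_constant",
                "iol_power", "postop_se")
  for (col in intersect(num_cols, names(cohort))) {
    cohort[[col]] <- as.numeric(cohort[[col]])
  }
  if ("has_stable_refraction" %in% names(cohort)) {
    cohort$has_stable_refraction <- as.logical(cohort$has_stable_refraction)
  }
  validate_cohort(cohort)
  cohort
}

#' Write a cohort table to CSV
#'
#' @param cohort A cohort data.frame.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full axial-length correction study on a cohort
#'
#' Wires the stages together: descriptive biometry summaries, paired
#' AL/keratometry comparisons per measurement mode, Bland-Altman
#' agreement for the pre/post mode pairs, the formula x option
#' prediction-error table with and without mean-error zeroing, the
#' optimized-constant table, and the ALc regression of the postoperative
#' pseudophakic reading on the preoperative phakic reading. Deterministic
#' given the cohort and configuration; optionally writes CSV/JSON files.
#'
#' @param cohort A cohort data.frame (or a path readable by
#'   [read_cohort()]).
#' @param formulas Formulas to evaluate, from [formula_ids()].
#' @param constants Starting [lens_constants()].
#' @param options AL options to evaluate.
#' @param out_dir Optional directory for CSV/JSON outputs.
#' @return List with `table1` (biometry summaries and paired tests),
#'   `bland_altman` (per mode pair), `table2` (prediction-error
#'   summaries), `table3` (optimized constants), `alc` (the fitted
#'   `al_correction`).
#' @export
run_study <- function(cohort, formulas = formula_ids(),
                      constants = lens_constants(119.30),
                      options = al_options(), out_dir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  validate_cohort(cohort)
  op <- cohort[cohort$eye_role == "operated", ]
  fe <- cohort[cohort$eye_role == "fellow", ]

  msd <- function(x) c(mean = mean(x, na.rm = TRUE),
                       sd = stats::sd(x, na.rm = TRUE))
  pt_or_na <- function(x, y) {
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 2) return(NA_real_)
    paired_t(x[ok], y[ok])$p_value
  }
  table1 <- data.frame(
    parameter = c("AL operated pre (Ph)", "AL operated post (Ps)",
                  "AL operated post (Ap)", "AL fellow pre", "AL fellow post",
                  "Km operated pre", "Km operated post",
                  "Km fellow pre", "Km fellow post"),
    mean = c(msd(op$al_pre_phakic)[1], msd(op$al_post_pseudophakic)[1],
             msd(op$al_post_aphakic)[1], msd(fe$al_pre_phakic)[1],
             msd(fe$al_post_repeat)[1], msd(op$km_pre)[1], msd(op$km_post)[1],
             msd(fe$km_pre)[1], msd(fe$km_post)[1]),
    sd = c(msd(op$al_pre_phakic)[2], msd(op$al_post_pseudophakic)[2],
           msd(op$al_post_aphakic)[2], msd(fe$al_pre_phakic)[2],
           msd(fe$al_post_repeat)[2], msd(op$km_pre)[2], msd(op$km_post)[2],
           msd(fe$km_pre)[2], msd(fe$km_post)[2]),
    p_vs_pre = c(NA, pt_or_na(op$al_post_pseudophakic, op$al_pre_phakic),
                 pt_or_na(op$al_post_aphakic, op$al_pre_phakic), NA,
                 pt_or_na(fe$al_post_repeat, fe$al_pre_phakic), NA,
                 pt_or_na(op$km_post, op$km_pre), NA,
                 pt_or_na(fe$km_post, fe$km_pre)),
    stringsAsFactors = FALSE)

  ba <- list(
    ps_vs_ph = bland_altman(op$al_post_pseudophakic, op$al_pre_phakic),
    ap_vs_ph = bland_altman(op$al_post_aphakic, op$al_pre_phakic),
    fellow_post_vs_pre = bland_altman(fe$al_post_repeat, fe$al_pre_phakic))

  table2 <- evaluate_options(cohort, formulas, constants, options,
                             optimize = TRUE)
  table3 <- table2[, c("formula", "al_option", "optimized_constant")]

  alc <- fit_al_correction(op$al_pre_phakic, op$al_post_pseudophakic)

  out <- list(table1 = table1, bland_altman = ba, table2 = table2,
              table3 = table3, alc = alc)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(table1, file.path(out_dir, "table1.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(table2, file.path(out_dir, "table2.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(table3, file.path(out_dir, "table3.csv"),
                     row.names = FALSE, na = "")
    ba_df <- data.frame(
      pair = names(ba),
      bias = vapply(ba, `[[`, numeric(1), "bias"),
      loa_low = vapply(ba, `[[`, numeric(1), "loa_low"),
      loa_high = vapply(ba, `[[`, numeric(1), "loa_high"),
      stringsAsFactors = FALSE)
    utils::write.csv(ba_df, file.path(out_dir, "bland_altman.csv"),
                     row.names = FALSE)
    writeLines(sprintf('{"intercept": %.10g, "slope": %.10g, "r_squared": %.10g}',
                       alc$intercept, alc$slope, alc$r_squared),
               file.path(out_dir, "alc.json"))
  }
  out
}
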