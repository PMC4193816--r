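#' Framingham risk model coefficients
#'
#' The published continuous-variable Framingham general cardiovascular risk
#' model (sex-specific Cox regressions on ln-transformed continuous
#' covariates: age, total cholesterol, HDL cholesterol, systolic blood
#' pressure; smoking and diabetes as categorical terms), embedded as a
#' versioned constant table. Cholesterol enters in mg/dl; the risk functions
#' convert from mmol/l (factor 38.67). Blood-pressure treatment status is not
#' modelled by this package (the untreated SBP coefficient is used).
#'
#' @return A tibble with one row per sex: baseline 10-year survival `s0`,
#'   mean linear predictor `mean_lp`, and the six coefficients.
#' @export
framingham_coefficients <- function() {
  tibble::tibble(
    sex = c("male", "female"),
    s0 = c(0.88936, 0.95012),
    mean_lp = c(23.9802, 26.1931),
    ln_age = c(3.06117, 2.32888),
    ln_tc = c(1.12370, 1.20904),
    ln_hdl = c(-0.93263, -0.70833),
    ln_sbp = c(1.93303, 2.76157),
    smoker = c(0.65451, 0.52873),
    diabetes = c(0.57367, 0.69154)
  )
}

#' Ten-year Framingham risk
#'
#' Computes the 10-year cardiovascular event probability (percent) for each
#' subject from age, total and HDL cholesterol and systolic blood pressure as
#' continuous variables and sex, diabetes and current smoking as categorical
#' variables, using the embedded coefficient table
#' ([framingham_coefficients()]): `risk = 1 - s0 ^ exp(lp - mean_lp)` with
#' `lp` the ln-scale linear predictor.
#'
#' @param data Subject tibble with columns `sex` (`"male"`/`"female"`), `age`
#'   (years), `tc_mmol`, `hdl_mmol` (mmol/l), `sbp` (mmHg), `smoker`,
#'   `diabetes` (logical). A missing column or missing value raises an error
#'   naming the covariate.
#' @return `data` with an `frs_pct` column (percent, in `[0, 100]`).
#' @export
framingham_risk <- function(data) {
  req <- c("sex", "age", "tc_mmol", "hdl_mmol", "sbp", "smoker", "diabetes")
  for (v in req) {
    if (!v %in% names(data)) {
      stop("Framingham risk: missing covariate `", v, "`.", call. = FALSE)
    }
    if (anyNA(data[[v]])) {
      stop("Framingham risk: missing values in covariate `", v, "`.",
           call. = FALSE)
    }
  }
  if (!all(data$sex %in% c("male", "female"))) {
    stop("Framingham risk: `sex` must be \"male\" or \"female\".",
         call. = FALSE)
  }
  co <- framingham_coefficients()
  i <- match(data$sex, co$sex)
  lp <- co$ln_age[i] * log(data$age) +
    co$ln_tc[i] * log(data$tc_mmol * 38.67) +
    co$ln_hdl[i] * log(data$hdl_mmol * 38.67) +
    co$ln_sbp[i] * log(data$sbp) +
    co$smoker[i] * as.numeric(data$smoker) +
    co$diabetes[i] * as.numeric(data$diabetes)
  risk <- 100 * (1 - co$s0[i]^exp(lp - co$mean_lp[i]))
  data$frs_pct <- pmin(pmax(risk, 0), 100)
  data
}
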