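#' Covariate coding for proportional transition intensities
#'
#' Covariate effects act multiplicatively on transition intensities,
#' `q_rs(z) = exp(alpha_rs + beta_rs . z)`, where `z` is the coded deviation
#' of an individual's profile from the reference ("typical") profile. The
#' default coding fixes the reference at a 70-year-old woman with femoral
#' neck BMD T-score -1.5, BMI 26.6 kg/m^2, no fall history, no prior
#' fracture and no comorbidities, and scales the continuous covariates so
#' that one coded unit equals:
#'
#' * `age_at_event`: +5 years of age at state entry (deviation from 70);
#' * `fnbmd_tscore`: one SD *lower* T-score (deviation below -1.5), so a
#'   positive coefficient means lower BMD carries higher risk;
#' * `bmi`: +5 kg/m^2 (deviation from 26.6);
#' * `sex` and all binary covariates: indicator 0/1 with 0 the reference
#'   (female, absent).
#'
#' The units are configurable because published hazard ratios do not always
#' state their per-unit scale; pass different `center`/`scale` values to
#' match whichever scale your coefficients are on.
#'
#' @param age_center,age_scale Reference age (years) and years per coded unit.
#' @param tscore_center,tscore_scale Reference T-score and signed T-score
#'   change per coded unit (`-1` means "per SD lower").
#' @param bmi_center,bmi_scale Reference BMI (kg/m^2) and kg/m^2 per unit.
#' @return A named list of `(center, scale)` pairs, class `msm_coding`.
#' @export
#' @examples
#' covariate_coding()
covariate_coding <- function(age_center = 70, age_scale = 5,
                             tscore_center = -1.5, tscore_scale = -1,
                             bmi_center = 26.6, bmi_scale = 5) {
  binaries <- c("sex", "falls", "prior_fracture", "cardiovascular", "cancer",
                "neurological", "rheumatoid", "respiratory", "diabetes")
  coding <- c(
    list(
      age_at_event = list(center = age_center, scale = age_scale),
      fnbmd_tscore = list(center = tscore_center, scale = tscore_scale),
      bmi = list(center = bmi_center, scale = bmi_scale)
    ),
    setNames(
      lapply(binaries, function(x) list(center = 0, scale = 1)),
      binaries
    )
  )
  structure(coding, class = "msm_coding")
}

#' The reference ("typical") covariate profile
#'
#' The profile at which all coded covariates are zero, so that baseline
#' intensities apply directly: a woman aged 70 at state entry, femoral neck
#' BMD T-score -1.5, BMI 26.6, no fall in the past 12 months, no prior
#' fracture, no comorbidities. Any field can be overridden.
#'
#' @param ... Named overrides, e.g. `sex = "male"`, `fnbmd_tscore = -2.5`.
#' @return A one-row tibble.
#' @export
#' @examples
#' reference_profile(sex = "male", age_at_event = 80)
reference_profile <- function(...) {
  prof <- tibble::tibble(
    sex = "female", age_at_event = 70, fnbmd_tscore = -1.5, bmi = 26.6,
    falls = 0L, prior_fracture = 0L, cardiovascular = 0L, cancer = 0L,
    neurological = 0L, rheumatoid = 0L, respiratory = 0L, diabetes = 0L
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(prof))
    if (length(unknown)) {
      abort(paste0("Unknown profile field(s): ", toString(unknown)))
    }
    for (nm in names(dots)) prof[[nm]] <- dots[[nm]]
  }
  prof
}

# Numeric 0/1 male indicator from whatever encoding `sex` arrives in.
sex_indicator <- function(sex) {
  if (is.numeric(sex)) return(as.numeric(sex))
  tolower(as.character(sex)) %in% c("male", "m", "men", "1")
}

# Code a data frame of profiles into the deviation matrix z (n x k) for the
# requested covariates. Unknown covariate names are a coding error.
code_covariates <- function(data, covariates, coding = covariate_coding()) {
  if (!length(covariates)) {
    return(matrix(numeric(), nrow = nrow(data), ncol = 0))
  }
  unknown <- setdiff(covariates, names(coding))
  if (length(unknown)) {
    abort(paste0("No coding defined for covariate(s): ", toString(unknown)))
  }
  missing_cols <- setdiff(covariates, names(data))
  if (length(missing_cols)) {
    abort(paste0("Profile/data lacks covariate(s): ", toString(missing_cols)))
  }
  z <- vapply(covariates, function(nm) {
    x <- data[[nm]]
    if (nm == "sex") x <- sex_indicator(x)
    sc <- coding[[nm]]
    (as.numeric(x) - sc$center) / sc$scale
  }, numeric(nrow(data)))
  z <- matrix(z, nrow = nrow(data), ncol = length(covariates),
              dimnames = list(NULL, covariates))
  if (any(!is.finite(z))) {
    abort("Non-finite coded covariate values; check the profile.")
  }
  z
}

#' Linear predictor of a covariate profile
#'
#' Computes `beta . z`, the log hazard-ratio contribution of a profile's
#' coded deviation from the reference profile. The reference profile maps
#' to zero for any coefficient vector.
#'
#' @param profile A one-row data frame (see [reference_profile()]).
#' @param beta Named numeric vector of log hazard ratios per coded unit.
#' @param coding A [covariate_coding()] object.
#' @return A scalar.
#' @export
#' @examples
#' linear_predictor(reference_profile(fnbmd_tscore = -2.5),
#'                  c(fnbmd_tscore = log(1.16)))
linear_predictor <- function(profile, beta, coding = covariate_coding()) {
  if (!length(beta)) return(0)
  if (is.null(names(beta)) || any(!nzchar(names(beta)))) {
    abort("`beta` must be a named vector.")
  }
  z <- code_covariates(profile, names(beta), coding)
  drop(z %*% beta)
}
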