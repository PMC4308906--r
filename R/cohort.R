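#' Derive anthropometric indices
#'
#' Adds body-mass index, waist-to-hip ratio and waist-to-stature ratio columns
#' to a subject-level cohort table. Height, waist and hip circumference are in
#' centimetres, weight in kilograms; BMI converts height to metres internally.
#'
#' @param cohort data.frame with columns `height`, `weight`, `wc`, `hip`.
#' @return The input with `bmi` (kg/m^2), `whr` and `wsr` columns appended
#'   (recomputed if already present); original columns untouched.
#' @export
derive_indices <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  need <- c("height", "weight", "wc", "hip")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("derive_indices: missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!is.na(cohort$height) & cohort$height <= 0 |
               !is.na(cohort$hip) & cohort$hip <= 0)
  if (length(bad))
    stop("derive_indices: nonpositive height/hip in row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  cohort$bmi <- cohort$weight / (cohort$height / 100)^2
  cohort$whr <- cohort$wc / cohort$hip
  cohort$wsr <- cohort$wc / cohort$height
  cohort
}

#' Flag hypertension
#'
#' A subject is hypertensive when SBP >= 140 mmHg, DBP >= 90 mmHg, or they
#' self-report current antihypertensive medication. A missing medication flag
#' is treated as "no" for the outcome definition (listwise exclusion of
#' incomplete records is the job of [filter_complete()]).
#'
#' @param sbp systolic blood pressure, mmHg.
#' @param dbp diastolic blood pressure, mmHg.
#' @param on_htn_med "yes"/"no" (or logical); NA treated as "no".
#' @return integer vector of 0/1.
#' @export
flag_hypertension <- function(sbp, dbp, on_htn_med = "no") {
  if (!is.numeric(sbp) || !is.numeric(dbp))
    stop("flag_hypertension: sbp and dbp must be numeric")
  med <- if (is.logical(on_htn_med)) on_htn_med else on_htn_med == "yes"
  med[is.na(med)] <- FALSE
  as.integer(sbp >= 140 | dbp >= 90 | med)
}

#' Classify obesity by BMI (Chinese standard)
#'
#' Bands: normal `< 24`, overweight `[24, 28)`, obese `>= 28`.
#'
#' @param bmi numeric, kg/m^2.
#' @return factor with levels normal, overweight, obese.
#' @export
flag_obesity <- function(bmi) {
  stopifnot(is.numeric(bmi))
  cut(bmi, breaks = c(-Inf, 24, 28, Inf), right = FALSE,
      labels = c("normal", "overweight", "obese"))
}

.bst_labels <- c("Chilli", "Chilli pear-apple", "Chilli apple",
                 "Pear", "Pear-apple", "Apple",
                 "Big pear", "Big pear-apple", "Big apple")

#' Nine-type body-shape classification
#'
#' Classifies subjects into the nine body-shape types defined by crossing the
#' three BMI bands (<24, 24-28, >=28) with three sex-specific waist-to-hip
#' ratio bands (male <0.85 / 0.85-0.90 / >=0.90; female <0.80 / 0.80-0.85 /
#' >=0.85). Codes run 1-9; within a BMI band the code increases with WHR, and
#' codes 1/4/7, 2/5/8, 3/6/9 share a WHR band across BMI bands (Chilli, Pear,
#' Big pear families etc.). All bands are half-open `[lower, upper)` with the
#' top band closed below.
#'
#' @param bmi numeric, kg/m^2.
#' @param whr numeric waist-to-hip ratio.
#' @param sex character vector, "male"/"female".
#' @return data.frame with integer `code` (1-9) and character `label`.
#' @export
classify_body_shape <- function(bmi, whr, sex) {
  stopifnot(length(bmi) == length(whr), length(bmi) == length(sex))
  if (!all(sex %in% c("male", "female")))
    stop("classify_body_shape: sex must be 'male' or 'female'")
  bmi_band <- findInterval(bmi, c(24, 28)) # 0,1,2
  lo <- ifelse(sex == "male", 0.85, 0.80)
  hi <- ifelse(sex == "male", 0.90, 0.85)
  whr_band <- (whr >= lo) + (whr >= hi) # 0,1,2
  code <- as.integer(3L * bmi_band + whr_band + 1L)
  data.frame(code = code, label = .bst_labels[code],
             stringsAsFactors = FALSE)
}

#' Drop rows with missing required fields
#'
#' Listwise exclusion as applied to the survey data: any row missing one of
#' the required fields is removed, and the number removed per field reported.
#'
#' @param cohort data.frame.
#' @param required character vector of column names that must be non-missing.
#' @return list with `cohort` (retained rows), `removed` (count), and
#'   `removed_by_field` (named missing counts among removed rows).
#' @export
filter_complete <- function(cohort, required) {
  unknown <- setdiff(required, names(cohort))
  if (length(unknown))
    stop("filter_complete: unknown column(s): ", paste(unknown, collapse = ", "))
  if (!length(required))
    return(list(cohort = cohort, removed = 0L,
                removed_by_field = integer(0)))
  miss <- vapply(cohort[required], is.na, logical(nrow(cohort)))
  miss <- matrix(miss, nrow = nrow(cohort))
  drop <- rowSums(miss) > 0
  list(cohort = cohort[!drop, , drop = FALSE],
       removed = sum(drop),
       removed_by_field = stats::setNames(colSums(miss[drop, , drop = FALSE]),
                                          required))
}

#' Read / write a cohort CSV
#'
#' The cohort dialect is plain CSV, one row per subject, header with the
#' subject field names, empty cells for missing values. Units: height/wc/hip
#' in cm, weight in kg, blood pressure in mmHg. `read_cohort` applies the
#' eligibility filter (age >= 18) at load time.
#'
#' @param path file path.
#' @param min_age eligibility cutoff in years (default 18).
#' @return data.frame.
#' @export
read_cohort <- function(path, min_age = 18) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if ("age" %in% names(x)) x <- x[is.na(x$age) | x$age >= min_age, , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' @rdname read_cohort
#' @param cohort data.frame to write.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}
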