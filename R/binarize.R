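#' Binarize sIgE levels at the sensitization threshold
#'
#' Converts the cohort's quantitative sIgE levels (kU/L) into a binary
#' patients-by-molecules sensitization matrix. A level equal to or above
#' the threshold is marked 1, a lower level 0. The conventional cut-off
#' for HDM allergens is 0.35 kU/L; the comparison is inclusive (`>=`)
#' with no epsilon slack.
#'
#' @param cohort An `hdm_cohort`.
#' @param threshold Positive sensitization threshold in kU/L
#'   (default 0.35).
#' @return Integer 0/1 matrix with `rownames` = patient ids and
#'   `colnames` = the panel in canonical order.
#' @export
#' @examples
#' co <- generate_cohort(synthetic_config(n_patients = 20, seed = 1))
#' m <- binarize(co)
#' table(m)
binarize <- function(cohort, threshold = 0.35) {
  stopifnot(inherits(cohort, "hdm_cohort"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("threshold must be a single positive number (kU/L)", call. = FALSE)
  panel <- cohort_panel(cohort)
  levels <- as.matrix(as.data.frame(cohort)[, panel, drop = FALSE])
  m <- matrix(as.integer(levels >= threshold),
              nrow = nrow(levels), ncol = ncol(levels),
              dimnames = list(cohort$patient_id, panel))
  m
}

#' Classify age into the study's two age groups
#'
#' Children are patients strictly under 18 years; everyone else is an
#' adult. Exactly 18 years classifies as adult ("under 18" read as
#' strict). Fractional ages are accepted.
#'
#' @param age Numeric vector of ages in years, `0 <= age < 150`.
#' @return Character vector, `"child"` or `"adult"`.
#' @export
classify_age <- function(age) {
  if (!is.numeric(age) || anyNA(age))
    stop("age must be numeric and non-missing", call. = FALSE)
  if (any(age < 0)) stop("age must be non-negative", call. = FALSE)
  if (any(age >= 150)) stop("age must be below 150", call. = FALSE)
  ifelse(age < 18, "child", "adult")
}

# logical membership vector for a group over a cohort
.group_mask <- function(cohort, group = c("all", "child", "adult")) {
  group <- match.arg(group)
  if (group == "all") rep(TRUE, nrow(cohort))
  else classify_age(cohort$age) == group
}

#' Stratify a cohort and its sensitization matrix
#'
#' Splits patients into disjoint strata by age group, region, or the
#' age-by-region cross. The strata form a partition: every patient
#' appears in exactly one stratum and stratum sizes sum to the cohort
#' size. Sub-matrices stay row-aligned with their sub-cohorts.
#'
#' @param cohort An `hdm_cohort`.
#' @param matrix The binary matrix from [binarize()], row-aligned with
#'   `cohort`.
#' @param by `"age"`, `"region"`, or `"age_region"`.
#' @return Named list of strata; each element is a list with `cohort`
#'   and `matrix`. Age-by-region strata are named `"<region>/<group>"`.
#' @export
stratify <- function(cohort, matrix, by = c("age", "region", "age_region")) {
  by <- match.arg(by)
  .check_aligned(cohort, matrix)
  key <- switch(by,
    age = classify_age(cohort$age),
    region = cohort$region,
    age_region = paste(cohort$region, classify_age(cohort$age), sep = "/"))
  idx <- split(seq_len(nrow(cohort)), key)
  lapply(idx, function(i) {
    sub <- as.data.frame(cohort)[i, , drop = FALSE]
    list(cohort = new_cohort(sub, cohort_panel(cohort)),
         matrix = matrix[i, , drop = FALSE])
  })
}

#' Patients sensitized to at least one molecule
#'
#' The "sensitized to any HDM molecule" indicator used as the denominator
#' of every share in the analysis.
#'
#' @param matrix Binary sensitization matrix.
#' @return Integer 0/1 vector over patients (named by patient id).
#' @export
sensitized_mask <- function(matrix) {
  .check_binary(matrix)
  out <- as.integer(rowSums(matrix) > 0)
  names(out) <- rownames(matrix)
  out
}

.check_binary <- function(matrix) {
  if (!is.matrix(matrix) || !all(matrix %in% c(0L, 1L)))
    stop("expected a binary 0/1 sensitization matrix", call. = FALSE)
  invisible(matrix)
}

.check_aligned <- function(cohort, matrix) {
  .check_binary(matrix)
  if (nrow(matrix) != nrow(cohort) ||
      !identical(rownames(matrix), cohort$patient_id) ||
      !identical(colnames(matrix), cohort_panel(cohort)))
    stop("sensitization matrix is not aligned with the cohort", call. = FALSE)
  invisible(TRUE)
}
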