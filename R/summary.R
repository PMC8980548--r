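# Half-up rounding; base round() is round-half-even, which would turn
# e.g. 72.105 into 72.10 where reported tables print 72.11.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage share of a count within a group
#'
#' `100 * count / total`, rounded half-up to two decimals — the precision
#' at which sensitization shares are conventionally reported.
#'
#' @param count Non-negative integer count, `count <= total`.
#' @param total Positive integer denominator (patients sensitized to at
#'   least one molecule in the group).
#' @return Percentage with two decimals.
#' @export
#' @examples
#' compute_share(2106, 2875)  # 73.25
compute_share <- function(count, total) {
  if (any(total <= 0))
    stop("undefined denominator: total must be positive", call. = FALSE)
  if (any(count < 0) || any(count > total))
    stop("count must satisfy 0 <= count <= total", call. = FALSE)
  round_half_up(100 * count / total, 2)
}

#' Count of patients sensitized to at least one molecule, by group
#'
#' @param cohort An `hdm_cohort`.
#' @param matrix Binary matrix from [binarize()].
#' @param group `"all"`, `"child"`, or `"adult"`.
#' @return Integer count.
#' @export
total_sensitized <- function(cohort, matrix, group = c("all", "child", "adult")) {
  group <- match.arg(group)
  .check_aligned(cohort, matrix)
  keep <- .group_mask(cohort, group)
  sum(sensitized_mask(matrix)[keep])
}

#' Child-to-adult ratio of sensitized patients
#'
#' @param child_count,adult_count Sensitized counts per age group.
#' @return Ratio rounded half-up to two decimals.
#' @export
#' @examples
#' child_adult_ratio(1993, 882)  # 2.26
child_adult_ratio <- function(child_count, adult_count) {
  if (adult_count == 0)
    stop("ratio undefined: no sensitized adults", call. = FALSE)
  round_half_up(child_count / adult_count, 2)
}

#' Per-molecule sensitization summary
#'
#' For each panel molecule, within the requested age group: the number of
#' sensitized patients, their share among patients sensitized to at least
#' one molecule (not among all tested patients), and the mean and standard
#' deviation of sIgE among the molecule's positives only. Means are
#' restricted to positives because a sensitization summary describes the
#' level distribution of the sensitized, and including sub-threshold
#' values would drag every mean toward zero.
#'
#' @param cohort An `hdm_cohort`.
#' @param matrix Binary matrix from [binarize()], aligned with `cohort`.
#' @param group `"all"`, `"child"`, or `"adult"`.
#' @param sd_type `"population"` (divide by n, the default, matching the
#'   M±sigma convention) or `"sample"` (divide by n-1).
#' @return A data.frame with one row per molecule, sorted by
#'   `n_sensitized` descending (ties by canonical panel order):
#'   columns `molecule`, `group`, `n_sensitized`, `share_pct`,
#'   `mean_sige`, `sd_sige`. When the group has no sensitized patients,
#'   `share_pct` is `NA` (undefined), never 0. Molecules with no
#'   positives get `NA` mean/sd.
#' @export
sensitization_summary <- function(cohort, matrix,
                                  group = c("all", "child", "adult"),
                                  sd_type = c("population", "sample")) {
  group <- match.arg(group)
  sd_type <- match.arg(sd_type)
  .check_aligned(cohort, matrix)
  panel <- cohort_panel(cohort)
  keep <- .group_mask(cohort, group)
  sub_m <- matrix[keep, , drop = FALSE]
  sub_l <- as.matrix(as.data.frame(cohort)[keep, panel, drop = FALSE])
  denom <- sum(sensitized_mask(sub_m))

  n_sens <- colSums(sub_m)
  stats_fun <- function(j) {
    v <- sub_l[sub_m[, j] == 1L, j]
    if (length(v) == 0L) return(c(NA_real_, NA_real_))
    m <- mean(v)
    s <- if (length(v) == 1L) {
      if (sd_type == "population") 0 else NA_real_
    } else if (sd_type == "population") {
      sqrt(sum((v - m)^2) / length(v))
    } else {
      stats::sd(v)
    }
    c(m, s)
  }
  ms <- vapply(seq_along(panel), stats_fun, numeric(2))

  out <- data.frame(
    molecule = panel,
    group = group,
    n_sensitized = as.integer(n_sens),
    share_pct = if (denom > 0) compute_share(as.integer(n_sens), denom)
                else NA_real_,
    mean_sige = ms[1L, ],
    sd_sige = ms[2L, ],
    stringsAsFactors = FALSE
  )
  ord <- order(-out$n_sensitized, match(out$molecule, panel))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_sensitized_any") <- denom
  out
}

#' tIgE summary for the sensitized group
#'
#' Mean and standard deviation of total IgE among patients sensitized to
#' at least one panel molecule. Rows with missing tIgE are excluded from
#' this summary only.
#'
#' @inheritParams sensitization_summary
#' @return A one-row data.frame: `group`, `n`, `mean_tige`, `sd_tige`
#'   (population sd).
#' @export
tige_summary <- function(cohort, matrix, group = c("all", "child", "adult")) {
  group <- match.arg(group)
  .check_aligned(cohort, matrix)
  keep <- .group_mask(cohort, group) & sensitized_mask(matrix) == 1L
  tige <- if (is.null(cohort$tige)) rep(NA_real_, nrow(cohort)) else cohort$tige
  v <- tige[keep]
  v <- v[!is.na(v)]
  data.frame(group = group, n = length(v),
             mean_tige = if (length(v)) mean(v) else NA_real_,
             sd_tige = if (length(v) > 1)
               sqrt(sum((v - mean(v))^2) / length(v)) else NA_real_)
}
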