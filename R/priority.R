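#' Configuration for the priority-molecule decision
#'
#' @param margin Absolute share margin in proportion units (default 0.05,
#'   i.e. 5 percentage points). If the top share exceeds the runner-up by
#'   more than this, the region has a single priority molecule.
#' @param p_similarity Relative closeness of p-values (default 0.05): the
#'   runner-up is kept when its upper-tail p differs from the maximum's p
#'   by at most this fraction of the maximum's p.
#' @param alpha Reporting significance level (default 0.002) recorded in
#'   the decision trace; not used as a gate unless `alpha_gate = TRUE`.
#' @param min_group_n Minimum number of sensitized patients for a
#'   region-group to be analyzed (default 3); smaller groups are excluded.
#' @param relative_margin If `TRUE`, interpret `margin` as a fraction of
#'   the top share instead of an absolute share difference.
#' @param alpha_gate If `TRUE`, molecules whose upper-tail p is below
#'   `alpha` (null of "another maximum at this level" rejected) cannot be
#'   retained as a second priority.
#' @return A list of class `priority_config`.
#' @export
priority_config <- function(margin = 0.05, p_similarity = 0.05,
                            alpha = 0.002, min_group_n = 3,
                            relative_margin = FALSE, alpha_gate = FALSE) {
  for (v in list(margin = margin, p_similarity = p_similarity, alpha = alpha))
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1)
      stop("margin, p_similarity and alpha must lie in (0, 1)", call. = FALSE)
  if (!is.numeric(min_group_n) || min_group_n < 1)
    stop("min_group_n must be >= 1", call. = FALSE)
  structure(list(margin = margin, p_similarity = p_similarity,
                 alpha = alpha, min_group_n = as.integer(min_group_n),
                 relative_margin = isTRUE(relative_margin),
                 alpha_gate = isTRUE(alpha_gate)),
            class = "priority_config")
}

#' Per-molecule sensitization shares for one region-group
#'
#' For every panel molecule, the number of the region-group's patients
#' positive to it divided by the number of its patients positive to at
#' least one panel molecule. Molecules nobody is positive to keep share
#' 0 in the series.
#'
#' @param cohort An `hdm_cohort`.
#' @param matrix Binary matrix from [binarize()], aligned with `cohort`.
#' @param region Region label present in the cohort (or `NULL` for the
#'   whole cohort).
#' @param group `"all"`, `"child"`, or `"adult"`.
#' @return A list of class `share_series`: `region`, `group`, `shares`
#'   (named numeric vector over the panel, in \[0,1\]), `counts`,
#'   `n_sensitized`.
#' @export
region_shares <- function(cohort, matrix, region = NULL,
                          group = c("all", "child", "adult")) {
  group <- match.arg(group)
  .check_aligned(cohort, matrix)
  keep <- .group_mask(cohort, group)
  if (!is.null(region)) {
    if (!region %in% cohort_regions(cohort))
      stop("region '", region, "' not present in cohort", call. = FALSE)
    keep <- keep & cohort$region == region
  }
  sub <- matrix[keep, , drop = FALSE]
  sens <- sensitized_mask(sub) == 1L
  n_sens <- sum(sens)
  counts <- colSums(sub[sens, , drop = FALSE])
  shares <- if (n_sens > 0) counts / n_sens else counts * 0
  structure(list(region = if (is.null(region)) "(all)" else region,
                 group = group,
                 shares = shares,
                 counts = as.integer(counts),
                 n_sensitized = n_sens),
            class = "share_series")
}

#' One-sample upper-tail Student's t-test
#'
#' Tests whether the mean of a short series exceeds a hypothesized value,
#' from the closed form: `t = (mean - popmean) / (s / sqrt(n))` with the
#' sample standard deviation `s` (n-1 denominator), and
#' `p = P(T_{n-1} >= t)`. This is the right-tail test used to ask, for a
#' series of per-molecule shares, whether values as large as a given
#' share are surprising — i.e. whether "another maximum" exists above it.
#'
#' A constant series has an undefined t statistic; the degenerate
#' convention is `p = 1` when `mean <= popmean` and `p = 0` otherwise,
#' flagged in the result.
#'
#' @param series Numeric vector, length >= 2.
#' @param popmean Hypothesized mean.
#' @return A list: `t` (statistic, `NA` when degenerate), `p` (upper-tail
#'   p-value in \[0,1\]), `df`, `degenerate` (logical).
#' @export
#' @examples
#' ttest_one_sample_greater(c(0.2, 0.4, 0.6), 0.4)  # t = 0, p = 0.5
ttest_one_sample_greater <- function(series, popmean) {
  if (!is.numeric(series) || length(series) < 2L || anyNA(series))
    stop("series must be numeric, length >= 2, without NA", call. = FALSE)
  n <- length(series)
  m <- mean(series)
  s <- stats::sd(series)
  if (s == 0) {
    return(list(t = NA_real_, p = if (m <= popmean) 1 else 0,
                df = n - 1L, degenerate = TRUE))
  }
  t_stat <- (m - popmean) / (s / sqrt(n))
  list(t = t_stat, p = stats::pt(t_stat, df = n - 1L, lower.tail = FALSE),
       df = n - 1L, degenerate = FALSE)
}

#' Priority molecules for one region-group
#'
#' Implements the margin-and-t-test decision for a region-group's share
#' series. In order:
#' \enumerate{
#'   \item Exclusion: no sensitized patients (`no_sensitized`) or fewer
#'     than `min_group_n` of them (`below_min_n`).
#'   \item Find the absolute maximum m1 and second maximum m2 of the
#'     shares; ties resolve by canonical panel order.
#'   \item If `share(m1) - share(m2)` exceeds the margin, m1 alone is the
#'     priority molecule (`margin_single`).
#'   \item Otherwise the pair is provisional and the t-step decides: for
#'     every molecule with positive share, the upper-tail p of
#'     [ttest_one_sample_greater()] on the full share series at that
#'     molecule's own share is computed. m2 is retained iff
#'     `|p(m2) - p(m1)| / p(m1) <= p_similarity` — its p is essentially as
#'     large as the maximum's, so the null that only m1 reflects the
#'     region's sensitization is not supported. Retained: priority
#'     `[m1, m2]` (`margin_equal_pair` when the shares are exactly equal,
#'     else `ttest_pair`); not retained: `[m1]` (`ttest_single`). A gap
#'     exactly equal to the margin counts as "not exceeding" it and goes
#'     through the t-step.
#' }
#'
#' @param series A `share_series` from [region_shares()].
#' @param config A [priority_config()].
#' @return A list of class `priority_decision`: `region`, `group`,
#'   `priority` (character vector, length 0-2), `excluded`,
#'   `excluded_reason` (`"none"`, `"no_sensitized"`, `"below_min_n"`),
#'   `rule_path`, and `trace` (first/second maxima with shares, whether
#'   the margin rule fired, the p-value map, alpha annotation).
#' @export
priority_molecules <- function(series, config = priority_config()) {
  stopifnot(inherits(series, "share_series"),
            inherits(config, "priority_config"))
  shares <- series$shares
  panel <- names(shares)
  base <- list(region = series$region, group = series$group,
               n_sensitized = series$n_sensitized)

  if (series$n_sensitized == 0L)
    return(.priority_decision(base, character(0), TRUE, "no_sensitized",
                              "excluded", NULL, config))
  if (series$n_sensitized < config$min_group_n)
    return(.priority_decision(base, character(0), TRUE, "below_min_n",
                              "excluded", NULL, config))
  if (all(shares <= 0))
    stop("inconsistent share series: sensitized patients present but all ",
         "shares are zero", call. = FALSE)

  # maxima with canonical-order tie-breaks: order by share desc, then
  # panel position
  ord <- order(-shares, seq_along(shares))
  m1 <- panel[ord[1L]]
  m2 <- panel[ord[2L]]
  s1 <- shares[[ord[1L]]]
  s2 <- shares[[ord[2L]]]
  gap <- s1 - s2
  margin <- if (config$relative_margin) config$margin * s1 else config$margin

  trace <- list(first_max = list(molecule = m1, share = s1),
                second_max = list(molecule = m2, share = s2),
                margin = margin, margin_rule_fired = FALSE,
                p_values = NULL, alpha = config$alpha)

  if (gap > margin) {
    trace$margin_rule_fired <- TRUE
    return(.priority_decision(base, m1, FALSE, "none", "margin_single",
                              trace, config))
  }

  # t-step over molecules with positive share, sample = the full series
  pos <- panel[shares > 0]
  p_values <- vapply(pos, function(mol) {
    ttest_one_sample_greater(unname(shares), shares[[mol]])$p
  }, numeric(1))
  trace$p_values <- p_values

  retained <- FALSE
  if (s2 > 0) {
    p1 <- p_values[[m1]]
    p2 <- p_values[[m2]]
    retained <- if (p1 == 0) p2 == 0 else abs(p2 - p1) / p1 <= config$p_similarity
    if (retained && config$alpha_gate && p2 < config$alpha) retained <- FALSE
  }
  if (retained) {
    path <- if (s1 == s2) "margin_equal_pair" else "ttest_pair"
    .priority_decision(base, c(m1, m2), FALSE, "none", path, trace, config)
  } else {
    .priority_decision(base, m1, FALSE, "none", "ttest_single", trace, config)
  }
}

.priority_decision <- function(base, priority, excluded, reason, path,
                               trace, config) {
  structure(c(base, list(priority = priority, excluded = excluded,
                         excluded_reason = reason, rule_path = path,
                         trace = trace, config = config)),
            class = "priority_decision")
}

#' @export
print.priority_decision <- function(x, ...) {
  cat("<priority_decision> ", x$region, " / ", x$group, ": ", sep = "")
  if (x$excluded) cat("excluded (", x$excluded_reason, ")\n", sep = "")
  else cat(paste(x$priority, collapse = " + "),
           " [", x$rule_path, "]\n", sep = "")
  invisible(x)
}

#' Priority molecules for every region (or region-by-age cell)
#'
#' Applies [priority_molecules()] to each region of the cohort, either on
#' all patients or separately for children and adults. Excluded cells
#' (none or too few sensitized patients) are reported, never dropped.
#'
#' @param cohort An `hdm_cohort`.
#' @param matrix Binary matrix from [binarize()], aligned with `cohort`.
#' @param config A [priority_config()].
#' @param by `"all"` (one decision per region) or `"age_region"`
#'   (child and adult decisions per region).
#' @return A list of `priority_decision` objects, ordered by region label
#'   then group; deterministic across runs. Use [priority_table()] for a
#'   tabular view.
#' @export
classify_all_regions <- function(cohort, matrix, config = priority_config(),
                                 by = c("all", "age_region")) {
  by <- match.arg(by)
  .check_aligned(cohort, matrix)
  regions <- cohort_regions(cohort)
  groups <- if (by == "all") "all" else c("child", "adult")
  out <- list()
  for (r in regions) {
    for (g in groups) {
      series <- region_shares(cohort, matrix, region = r, group = g)
      out[[paste(r, g, sep = "/")]] <- priority_molecules(series, config)
    }
  }
  out
}

#' Tabulate priority decisions
#'
#' @param decisions List of `priority_decision` objects from
#'   [classify_all_regions()].
#' @return A data.frame with one row per decision: `region`, `group`,
#'   `priority_1`, `priority_2` (empty string when absent), `share_1`,
#'   `share_2`, `rule_path`, `excluded_reason`, `n_sensitized`.
#' @export
priority_table <- function(decisions) {
  rows <- lapply(decisions, function(d) {
    tr <- d$trace
    data.frame(
      region = d$region, group = d$group,
      priority_1 = if (length(d$priority) >= 1L) d$priority[1L] else "",
      priority_2 = if (length(d$priority) >= 2L) d$priority[2L] else "",
      share_1 = if (!is.null(tr)) tr$first_max$share else NA_real_,
      share_2 = if (!is.null(tr)) tr$second_max$share else NA_real_,
      rule_path = d$rule_path,
      excluded_reason = d$excluded_reason,
      n_sensitized = d$n_sensitized,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tabulate the p-value traces of priority decisions
#'
#' @param decisions List of `priority_decision` objects.
#' @return A data.frame with one row per (region, group, molecule) for
#'   decisions whose t-step ran: columns `region`, `group`, `molecule`,
#'   `share`, `p_value`.
#' @export
priority_trace_table <- function(decisions) {
  rows <- lapply(decisions, function(d) {
    pv <- d$trace$p_values
    if (is.null(pv) || length(pv) == 0L) return(NULL)
    data.frame(region = d$region, group = d$group,
               molecule = names(pv),
               p_value = unname(pv),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L)
    return(data.frame(region = character(), group = character(),
                      molecule = character(), p_value = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
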