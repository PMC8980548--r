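#' Enumerate exact sensitization profiles
#'
#' A patient's sensitization profile is the exact set of panel molecules
#' they are positive to. Each sensitized patient contributes to exactly
#' one profile (their full positive set, never its subsets), so profile
#' counts sum to the number of sensitized patients. All-negative patients
#' are outside the profile space.
#'
#' @param cohort An `hdm_cohort`.
#' @param matrix Binary matrix from [binarize()], aligned with `cohort`.
#' @param group `"all"`, `"child"`, or `"adult"`.
#' @return A data.frame of class `hdm_profiles`, one row per distinct
#'   profile, sorted by count descending with ties broken by fewer
#'   members then canonical panel order: columns `profile` (molecule
#'   names joined by `"+"` in panel order), `n_members`, `n`,
#'   `share_pct` (share of the group's sensitized-to-any patients).
#' @export
enumerate_profiles <- function(cohort, matrix,
                               group = c("all", "child", "adult")) {
  group <- match.arg(group)
  .check_aligned(cohort, matrix)
  panel <- cohort_panel(cohort)
  keep <- .group_mask(cohort, group)
  sub <- matrix[keep, , drop = FALSE]
  sub <- sub[rowSums(sub) > 0, , drop = FALSE]

  if (nrow(sub) == 0L) {
    out <- data.frame(profile = character(), n_members = integer(),
                      n = integer(), share_pct = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    keys <- apply(sub, 1L, function(r) paste(panel[r == 1L], collapse = "+"))
    tab <- table(keys)
    profile <- names(tab)
    n <- as.integer(tab)
    n_members <- lengths(strsplit(profile, "+", fixed = TRUE))
    # tie-break: larger count, then fewer members, then first-member
    # position in the canonical panel (profile labels are panel-ordered,
    # so lexicographic order on the member index vector works)
    member_rank <- vapply(strsplit(profile, "+", fixed = TRUE), function(m) {
      paste(sprintf("%02d", match(m, panel)), collapse = "")
    }, character(1))
    ord <- order(-n, n_members, member_rank)
    out <- data.frame(profile = profile[ord],
                      n_members = as.integer(n_members[ord]),
                      n = n[ord],
                      share_pct = compute_share(n[ord], nrow(sub)),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "group") <- group
  attr(out, "n_sensitized") <- nrow(sub)
  attr(out, "panel") <- panel
  class(out) <- c("hdm_profiles", "data.frame")
  out
}

#' @export
print.hdm_profiles <- function(x, ...) {
  cat("<hdm_profiles> group=", attr(x, "group"), ": ",
      nrow(x), " distinct profiles in ", attr(x, "n_sensitized"),
      " sensitized patients\n", sep = "")
  print(as.data.frame(utils::head(x, 10L)))
  invisible(x)
}

#' Mono- vs poly-sensitization
#'
#' A profile with exactly one member molecule is monosensitization;
#' two or more is polysensitization (co-sensitization).
#'
#' @param members Character vector of molecule names (one profile), or a
#'   `"+"`-joined profile label.
#' @return `"mono"` or `"poly"`.
#' @export
classify_profile <- function(members) {
  if (length(members) == 1L && grepl("+", members, fixed = TRUE))
    members <- strsplit(members, "+", fixed = TRUE)[[1L]]
  if (length(members) == 0L || any(!nzchar(members)))
    stop("a profile must have at least one member molecule", call. = FALSE)
  if (length(members) == 1L) "mono" else "poly"
}

#' Top-ranked sensitization profiles
#'
#' @param profiles An `hdm_profiles` table from [enumerate_profiles()].
#' @param k Number of profiles to return (`k >= 1`); if `k` exceeds the
#'   number of distinct profiles, all are returned.
#' @return The first `k` rows under the table's deterministic ordering.
#' @export
top_profiles <- function(profiles, k) {
  stopifnot(inherits(profiles, "hdm_profiles"))
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    stop("k must be a positive integer", call. = FALSE)
  utils::head(as.data.frame(profiles), n = as.integer(k))
}
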