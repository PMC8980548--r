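# fixtures are built in code; nothing binary is stored on disk

# a tiny hand-written cohort over the full 11-molecule panel:
# P1 child, positive to Der f 2 + Der p 2; P2 adult, positive to Der p 23;
# P3 child, all-negative; P4 adult, positive to Der f 2 only
toy_cohort <- function() {
  panel <- hdm_panel()
  df <- data.frame(patient_id = c("P1", "P2", "P3", "P4"),
                   age = c(5, 40, 17, 20),
                   region = c("North", "North", "South land", "South land"),
                   tige = c(120, NA, 35, 300),
                   stringsAsFactors = FALSE)
  for (mol in panel) df[[mol]] <- c(0.1, 0.2, 0.05, 0.0)
  df[df$patient_id == "P1", c("Der f 2", "Der p 2")] <- c(12.5, 8.1)
  df[df$patient_id == "P2", "Der p 23"] <- 0.35
  df[df$patient_id == "P4", "Der f 2"] <- 4.2
  new_cohort(df, panel)
}

# cohort built directly from a binary matrix: positives get level 1.0,
# negatives 0.0, ages/regions cycled
cohort_from_matrix <- function(mat, panel = colnames(mat),
                               ages = NULL, regions = NULL) {
  n <- nrow(mat)
  df <- data.frame(
    patient_id = sprintf("M%04d", seq_len(n)),
    age = if (is.null(ages)) rep(c(6, 30), length.out = n) else ages,
    region = if (is.null(regions)) rep("R1", n) else regions,
    stringsAsFactors = FALSE)
  for (j in seq_along(panel)) df[[panel[j]]] <- as.numeric(mat[, j])
  new_cohort(df, panel)
}

write_cohort_fixture <- function(cohort, path, dialect = "tab") {
  write_table(as.data.frame(cohort), path, dialect = dialect, digits = 4)
  path
}

# a small share series over an arbitrary panel, for priority tests
make_series <- function(shares, n_sensitized = 10L,
                        region = "R", group = "all") {
  structure(list(region = region, group = group,
                 shares = shares,
                 counts = as.integer(round(shares * n_sensitized)),
                 n_sensitized = as.integer(n_sensitized)),
            class = "share_series")
}

# independent quadrature oracle for the upper tail of Student's t:
# integrates the density written out from the gamma-function form
t_upper_tail_quadrature <- function(t_stat, df) {
  dens <- function(x)
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  if (!is.finite(t_stat)) return(if (t_stat > 0) 0 else 1)
  stats::integrate(dens, t_stat, Inf, rel.tol = 1e-12,
                   abs.tol = 1e-14)$value
}

# deliberately plain re-implementation of the priority decision rules,
# used as the brute-force oracle; shares is a named vector, ties by the
# order of its names
oracle_priority <- function(shares, n_sensitized, margin = 0.05,
                            p_similarity = 0.05, min_n = 3) {
  if (n_sensitized == 0) return(list(priority = character(0),
                                     path = "excluded",
                                     reason = "no_sensitized"))
  if (n_sensitized < min_n) return(list(priority = character(0),
                                        path = "excluded",
                                        reason = "below_min_n"))
  if (all(shares <= 0)) stop("all-zero shares")
  panel <- names(shares)
  # find first and second maxima by explicit scan
  i1 <- 1L
  for (i in seq_along(shares)) if (shares[i] > shares[i1]) i1 <- i
  i2 <- NA_integer_
  for (i in seq_along(shares)) {
    if (i == i1) next
    if (is.na(i2) || shares[i] > shares[i2]) i2 <- i
  }
  s1 <- shares[[i1]]; s2 <- shares[[i2]]
  if (s1 - s2 > margin)
    return(list(priority = panel[i1], path = "margin_single",
                reason = "none"))
  # one-sample greater t-test, spelled out
  tp <- function(popmean) {
    n <- length(shares); m <- sum(shares) / n
    s <- sqrt(sum((shares - m)^2) / (n - 1))
    if (s == 0) return(if (m <= popmean) 1 else 0)
    tt <- (m - popmean) / (s / sqrt(n))
    stats::pt(tt, n - 1, lower.tail = FALSE)
  }
  keep <- FALSE
  if (s2 > 0) {
    p1 <- tp(s1); p2 <- tp(s2)
    keep <- if (p1 == 0) p2 == 0 else abs(p2 - p1) / p1 <= p_similarity
  }
  if (keep)
    list(priority = c(panel[i1], panel[i2]),
         path = if (s1 == s2) "margin_equal_pair" else "ttest_pair",
         reason = "none")
  else
    list(priority = panel[i1], path = "ttest_single", reason = "none")
}
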