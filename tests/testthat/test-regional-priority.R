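test_that("region shares divide molecule counts by the sensitized-to-any denominator", {
  panel <- c("A", "B")
  mat <- rbind(c(1L, 1L), c(1L, 0L), c(1L, 0L), c(0L, 1L), c(0L, 0L))
  colnames(mat) <- panel
  co <- cohort_from_matrix(mat, regions = rep("R1", 5))
  rownames(mat) <- co$patient_id
  ss <- region_shares(co, mat, "R1", "all")
  expect_equal(ss$n_sensitized, 4L)
  expect_equal(unname(ss$shares), c(3 / 4, 2 / 4))

  # region with nobody sensitized
  mat0 <- matrix(0L, 2, 2, dimnames = list(NULL, panel))
  co0 <- cohort_from_matrix(mat0, regions = rep("R1", 2))
  rownames(mat0) <- co0$patient_id
  ss0 <- region_shares(co0, mat0, "R1", "all")
  expect_equal(ss0$n_sensitized, 0L)
  expect_equal(unname(ss0$shares), c(0, 0))
  expect_error(region_shares(co0, mat0, "nowhere", "all"), "not present")
})

test_that("region shares agree with a brute-force recount on synthetic data", {
  cfg <- synthetic_config(n_patients = 30, seed = 21,
                          region_weights = c(R1 = 0.5, R2 = 0.5))
  co <- generate_cohort(cfg)
  m <- binarize(co)
  for (r in cohort_regions(co)) {
    ss <- region_shares(co, m, r, "all")
    rows <- which(co$region == r & rowSums(m) > 0)
    expect_equal(ss$n_sensitized, length(rows))
    for (mol in hdm_panel())
      expect_equal(ss$shares[[mol]],
                   if (length(rows)) sum(m[rows, mol]) / length(rows) else 0)
  }
})

test_that("the one-sample greater t-test matches its closed form and limits", {
  r <- ttest_one_sample_greater(c(0.2, 0.4, 0.6), 0.4)
  expect_equal(r$t, 0)
  expect_equal(r$p, 0.5)   # mean equal to popmean: one-sided p is exactly 1/2

  # monotone in popmean, approaching 1 in the upper limit
  s <- c(0.1, 0.5, 0.3, 0.9, 0.2)
  ps <- vapply(c(-10, 0, 0.4, 2, 100),
               function(mu) ttest_one_sample_greater(s, mu)$p, numeric(1))
  expect_true(all(diff(ps) >= 0))
  expect_gt(ps[length(ps)], 1 - 1e-9)

  # degenerate constant series
  d <- ttest_one_sample_greater(c(0.3, 0.3, 0.3), 0.3)
  expect_true(d$degenerate)
  expect_equal(d$p, 1)
  expect_equal(ttest_one_sample_greater(c(0.3, 0.3), 0.1)$p, 0)
  expect_error(ttest_one_sample_greater(0.5, 0), "length")
})

test_that("t-test p-values agree with a quadrature oracle to 1e-8", {
  set.seed(99)
  for (i in 1:50) {
    s <- runif(5)
    mu <- runif(1)
    r <- ttest_one_sample_greater(s, mu)
    expect_equal(r$p, t_upper_tail_quadrature(r$t, r$df), tolerance = 1e-8)
  }
})

test_that("the margin rule and t-step select 1-2 priority molecules", {
  panel3 <- c("A", "B", "C")

  # clear gap: single priority
  d <- priority_molecules(make_series(
    stats::setNames(c(0.60, 0.50, 0.10), panel3), n_sensitized = 20))
  expect_identical(d$priority, "A")
  expect_identical(d$rule_path, "margin_single")
  expect_true(d$trace$margin_rule_fired)

  # exactly equal maxima: both molecules kept
  d2 <- priority_molecules(make_series(
    stats::setNames(c(0.50, 0.50, 0.10), panel3), n_sensitized = 20))
  expect_identical(d2$priority, c("A", "B"))
  expect_identical(d2$rule_path, "margin_equal_pair")

  # near-tie across an 11-molecule series: verify the branch against the
  # closed form computed here
  shares <- stats::setNames(c(0.52, 0.49, rep(0.10, 9)), hdm_panel())
  d3 <- priority_molecules(make_series(shares, n_sensitized = 50))
  p1 <- ttest_one_sample_greater(unname(shares), 0.52)$p
  p2 <- ttest_one_sample_greater(unname(shares), 0.49)$p
  if (abs(p2 - p1) / p1 <= 0.05) {
    expect_identical(d3$priority, names(shares)[1:2])
    expect_identical(d3$rule_path, "ttest_pair")
  } else {
    expect_identical(d3$priority, names(shares)[1])
    expect_identical(d3$rule_path, "ttest_single")
  }
  expect_equal(d3$trace$p_values[["Der f 1"]], p1)

  # p of the absolute maximum dominates p of any smaller share
  expect_true(all(d3$trace$p_values <= d3$trace$p_values[["Der f 1"]] + 1e-15))

  # exclusions
  e0 <- priority_molecules(make_series(
    stats::setNames(c(0, 0, 0), panel3), n_sensitized = 0L))
  expect_true(e0$excluded)
  expect_identical(e0$excluded_reason, "no_sensitized")
  e2 <- priority_molecules(make_series(
    stats::setNames(c(0.5, 0.5, 0), panel3), n_sensitized = 2L))
  expect_identical(e2$excluded_reason, "below_min_n")
  expect_error(priority_molecules(make_series(
    stats::setNames(c(0, 0, 0), panel3), n_sensitized = 5L)),
    "inconsistent")
})

test_that("priority decisions match the brute-force oracle on a share grid", {
  # coarse sweep here; the exhaustive grid runs in the acceptance suite
  panel3 <- c("A", "B", "C")
  grid <- seq(0, 1, by = 0.25)
  for (a in grid) for (b in grid) for (c in grid) {
    shares <- stats::setNames(c(a, b, c), panel3)
    if (all(shares == 0)) next
    d <- priority_molecules(make_series(shares, n_sensitized = 10L))
    o <- oracle_priority(shares, 10L)
    expect_identical(d$priority, unname(o$priority))
    expect_identical(d$rule_path, o$path)
  }
})

test_that("decisions are scale-free in the underlying counts", {
  set.seed(12)
  for (i in 1:20) {
    shares <- stats::setNames(round(runif(4), 2), c("A", "B", "C", "D"))
    if (all(shares == 0)) next
    d1 <- priority_molecules(make_series(shares, n_sensitized = 10L))
    d2 <- priority_molecules(make_series(shares, n_sensitized = 1000L))
    expect_identical(d1$priority, d2$priority)
    expect_identical(d1$rule_path, d2$rule_path)
  }
})

test_that("classify_all_regions reports a decision or exclusion per region", {
  panel <- c("A", "B")
  # R1: only A positives; R2: two sensitized patients; R3: none
  mat <- rbind(c(1L, 0L), c(1L, 0L), c(1L, 0L),
               c(1L, 1L), c(0L, 1L),
               c(0L, 0L))
  colnames(mat) <- panel
  co <- cohort_from_matrix(mat, regions = c("R1", "R1", "R1",
                                            "R2", "R2", "R3"))
  rownames(mat) <- co$patient_id
  dec <- classify_all_regions(co, mat, priority_config(), by = "all")
  expect_equal(length(dec), 3L)
  expect_identical(dec[["R1/all"]]$priority, "A")
  expect_identical(dec[["R2/all"]]$excluded_reason, "below_min_n")
  expect_identical(dec[["R3/all"]]$excluded_reason, "no_sensitized")

  tb <- priority_table(dec)
  expect_equal(nrow(tb), 3L)
  expect_identical(tb$priority_1, c("A", "", ""))

  # repeated runs are identical (no hidden randomness)
  dec2 <- classify_all_regions(co, mat, priority_config(), by = "all")
  expect_identical(priority_table(dec2), tb)

  # age x region decisions partition by group
  deca <- classify_all_regions(co, mat, priority_config(), by = "age_region")
  expect_equal(length(deca), 6L)
  expect_setequal(unique(priority_table(deca)$group), c("child", "adult"))
})
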