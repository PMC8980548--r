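test_that("share arithmetic matches half-up 2-decimal reporting", {
  expect_equal(compute_share(2106, 2875), 73.25)
  expect_equal(compute_share(1167, 1993), 58.55)
  expect_equal(compute_share(1553, 2875), 54.02)  # 54.017 rounds up
  expect_equal(compute_share(0, 10), 0)
  expect_equal(compute_share(10, 10), 100)
  # half-up, not banker's: 1/16000 = 0.00625% sits exactly on the
  # half-way point at two decimals and must round up
  expect_equal(compute_share(1, 16000), 0.01)
  expect_error(compute_share(1, 0), "denominator")
  expect_error(compute_share(5, 4), "count")
})

test_that("child/adult sensitized counts and their ratio are reported", {
  expect_equal(child_adult_ratio(1993, 882), 2.26)
  expect_equal(child_adult_ratio(50, 50), 1)
  expect_error(child_adult_ratio(10, 0), "undefined")

  co <- toy_cohort()
  m <- binarize(co)
  expect_equal(total_sensitized(co, m, "all"), 3L)
  expect_equal(total_sensitized(co, m, "child"), 1L)  # P3 is all-negative
  expect_equal(total_sensitized(co, m, "adult"), 2L)
})

test_that("per-molecule summary rows carry count, share, mean and sd", {
  # 4 patients, molecule X levels (0.1, 1.0, 3.0, 0.2); Y makes everyone
  # sensitized to at least one molecule
  panel <- c("X", "Y")
  df <- data.frame(patient_id = paste0("p", 1:4), age = 10, region = "R",
                   X = c(0.1, 1.0, 3.0, 0.2), Y = c(2, 2, 2, 2),
                   stringsAsFactors = FALSE)
  co <- new_cohort(df, panel)
  m <- binarize(co)
  s <- sensitization_summary(co, m, "all")
  x <- s[s$molecule == "X", ]
  expect_equal(x$n_sensitized, 2L)
  expect_equal(x$share_pct, 50)
  expect_equal(x$mean_sige, 2)
  expect_equal(x$sd_sige, 1)  # population sd of (1, 3)
  expect_equal(s[s$molecule == "X", "sd_sige"],
               1, tolerance = 1e-12)
  # sample sd available behind the flag
  s2 <- sensitization_summary(co, m, "all", sd_type = "sample")
  expect_equal(s2[s2$molecule == "X", "sd_sige"], sd(c(1, 3)))
  # rows sorted by n_sensitized descending
  expect_identical(s$molecule, c("Y", "X"))
})

test_that("empty groups report undefined shares and blank means", {
  panel <- c("X", "Y")
  df <- data.frame(patient_id = c("a", "b"), age = c(5, 6), region = "R",
                   X = c(0.1, 0.2), Y = c(0.1, 0.1),
                   stringsAsFactors = FALSE)
  co <- new_cohort(df, panel)
  m <- binarize(co)
  s <- sensitization_summary(co, m, "all")
  expect_true(all(is.na(s$share_pct)))   # nobody sensitized: undefined, not 0
  expect_true(all(is.na(s$mean_sige)))
  expect_equal(s$n_sensitized, c(0L, 0L))
  sa <- sensitization_summary(co, m, "adult")  # empty age group
  expect_true(all(is.na(sa$share_pct)))
})

test_that("summary counts agree with a brute-force recount on synthetic data", {
  co <- generate_cohort(synthetic_config(n_patients = 50, seed = 9))
  m <- binarize(co)
  s <- sensitization_summary(co, m, "all")
  df <- as.data.frame(co)
  for (mol in hdm_panel()) {
    manual <- sum(df[[mol]] >= 0.35)
    expect_equal(s$n_sensitized[s$molecule == mol], manual)
    if (manual > 0)
      expect_equal(s$mean_sige[s$molecule == mol],
                   mean(df[[mol]][df[[mol]] >= 0.35]))
  }
  # group invariants
  denom <- sum(rowSums(m) > 0)
  expect_true(sum(s$n_sensitized) >= total_sensitized(co, m, "all"))
  expect_equal(max(s$share_pct), s$share_pct[1])
  sc <- sensitization_summary(co, m, "child")
  sa <- sensitization_summary(co, m, "adult")
  for (mol in hdm_panel())
    expect_equal(s$n_sensitized[s$molecule == mol],
                 sc$n_sensitized[sc$molecule == mol] +
                   sa$n_sensitized[sa$molecule == mol])
  # means restricted to positives sit at or above the threshold
  expect_true(all(s$mean_sige[s$n_sensitized > 0] >= 0.35))
})

test_that("tIgE summary covers sensitized patients with recorded values", {
  co <- toy_cohort()
  m <- binarize(co)
  ts <- tige_summary(co, m, "all")
  # sensitized: P1 (120), P2 (NA), P4 (300) -> n = 2
  expect_equal(ts$n, 2L)
  expect_equal(ts$mean_tige, 210)
  expect_equal(ts$sd_tige, 90)  # population sd of (120, 300)
})
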