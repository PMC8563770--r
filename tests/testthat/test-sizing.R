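# Normal fits, FWHM brackets, the nine-design table, assignment rules,
# coverage, and scan-method agreement.

ref_table <- load_reference_table()

test_that("fit_normal uses moment estimates and the exact FWHM relation", {
  f <- fit_normal(c(1, 2, 3))
  expect_equal(f$mu, 2)
  expect_equal(f$sd, 1)
  expect_equal(f$fwhm, 2 * sqrt(2 * log(2)))
  expect_error(fit_normal(rep(5, 10)), "degenerate")
  expect_error(fit_normal(c(1, 2)), "at least 3")
  # large-sample FWHM of a standard normal approaches sqrt(8 log 2)
  set.seed(1)
  fbig <- fit_normal(rnorm(1e6))
  expect_equal(fbig$fwhm, sqrt(8 * log(2)), tolerance = 0.01)
})

test_that("build_size_brackets centres brackets on the FWHM boundaries", {
  # three values with sample mean 104.85 and sd 6.37 exactly
  vals <- c(104.85 - 6.37, 104.85, 104.85 + 6.37)
  br <- build_size_brackets(vals, half_width = 4.5)
  fwhm <- 2 * 6.37 * sqrt(2 * log(2))
  expect_equal(br$midpoint, 104.85 + c(-1, 0, 1) * fwhm / 2)
  expect_equal(br$midpoint, c(97.35, 104.85, 112.35), tolerance = 0.01)
  expect_equal(br$upper - br$lower, rep(9, 3))
  expect_equal(br$label, c("Small", "Medium", "Large"))
  # overlap width of adjacent brackets: 2*half_width - fwhm/2
  ov <- bracket_overlaps(br)
  expect_equal(nrow(ov), 2L)
  expect_equal(ov$upper - ov$lower, rep(2 * 4.5 - fwhm / 2, 2))
  # half_width < fwhm/4 makes brackets disjoint
  br2 <- build_size_brackets(vals, half_width = 0.9 * fwhm / 4)
  expect_equal(nrow(bracket_overlaps(br2)), 0L)
  # non-adjacent overlap is rejected
  expect_error(build_size_brackets(vals, half_width = fwhm / 2 + 0.1),
               "non-adjacent")
})

test_that("build_sizing_table produces nine cells at the expected centres", {
  ch <- synth_cohort(cohort_spec(n = 10000, seed = 11))
  tab <- build_sizing_table(ch)
  expect_s3_class(tab, "sizing_table")
  expect_equal(nrow(tab$shell_brackets), 3L)
  expect_equal(nrow(tab$profiles), 9L)
  fit <- fit_normal(ch$eye_to_chin)
  expect_equal(tab$shell_brackets$midpoint,
               fit$mu + c(-1, 0, 1) * fit$fwhm / 2, tolerance = 1e-9)
  expect_true(all(table(tab$profiles$shell) == 3))
  expect_true(all(is.finite(tab$profiles$A_mean)))
  # degenerate cohort propagates the scale failure
  same <- data.frame(subject_id = as.character(1:50), eye_to_chin = 105,
                     A = 23, sigma = 10)
  expect_error(build_sizing_table(same), "degenerate")
  # an under-populated shell is named
  sparse <- data.frame(subject_id = as.character(1:11),
                       eye_to_chin = c(rnorm(10, 100, 0.1), 200),
                       A = 23, sigma = rnorm(11, 10, 0.3))
  expect_error(suppressWarnings(build_sizing_table(sparse)), "members")
})

test_that("assignment reproduces the reference worked examples", {
  # overlap case: 100.5 lies in Small and Medium, but sigma 11.2 only fits
  # a Medium profile, so Medium (III) wins over the nearer Small shell
  a <- assign_design(list(eye_to_chin = 100.5, sigma = 11.2), ref_table)
  expect_equal(a$route, "SEMI_CUSTOM")
  expect_equal(a$shell, "Medium")
  expect_equal(a$profile, "III")
  expect_true(a$in_overlap)
  expect_gt(length(a$rationale), 2)

  b <- assign_design(list(eye_to_chin = 104.9, sigma = 10.2), ref_table)
  expect_equal(c(b$shell, b$profile), c("Medium", "II"))
  expect_false(b$in_overlap)

  # out of range at stage one: flagged for the fully-customised route
  c1 <- assign_design(list(eye_to_chin = 80, sigma = 10.2), ref_table)
  expect_equal(c1$route, "FULLY_CUSTOM")
  expect_true(is.na(c1$shell))
  # out of range at stage two
  c2 <- assign_design(list(eye_to_chin = 104.9, sigma = 14), ref_table)
  expect_equal(c2$route, "FULLY_CUSTOM")
})

test_that("assignment is total and shell choice is monotone in eye-to-chin", {
  set.seed(7)
  for (i in 1:200) {
    r <- assign_design(list(eye_to_chin = runif(1, 60, 140),
                            sigma = runif(1, 6, 14)), ref_table)
    expect_true(r$route %in% c("SEMI_CUSTOM", "FULLY_CUSTOM"))
    expect_equal(r$route == "SEMI_CUSTOM",
                 !is.na(r$shell) && !is.na(r$profile))
  }
  # sigma 10.2 is valid in every shell; the assigned shell never shrinks as
  # eye-to-chin grows
  ord <- c(Small = 1, Medium = 2, Large = 3)
  ecs <- seq(93, 116.5, by = 0.5)
  sh <- vapply(ecs, function(e)
    ord[[assign_design(list(eye_to_chin = e, sigma = 10.2), ref_table)$shell]],
    numeric(1))
  expect_true(all(diff(sh) >= 0))
})

test_that("every reference cell recaptures its own centre point", {
  sh <- ref_table$shell_brackets
  pr <- ref_table$profiles
  for (i in seq_len(nrow(pr))) {
    ec_mid <- sh$midpoint[match(pr$shell[i], sh$label)]
    r <- assign_design(list(eye_to_chin = ec_mid, sigma = pr$midpoint[i]),
                       ref_table)
    expect_equal(r$shell, pr$shell[i])
    expect_equal(r$profile, pr$label[i])
  }
})

test_that("the reference table midpoints match the printed limits", {
  # (92.8 + 101.8) / 2 = 97.3 exactly as printed
  expect_equal(ref_table$shell_brackets$midpoint[1], 97.3, tolerance = 1e-12)
  # printed midpoints agree with recomputed ones to one-decimal rounding
  expect_equal(ref_table$shell_brackets$midpoint,
               c(97.3, 104.9, 112.4), tolerance = 0.05 / 97)
})

test_that("coverage agrees with edge cases and the Gaussian closed form", {
  rec <- function(ec, sg, n) data.frame(subject_id = as.character(seq_len(n)),
                                        eye_to_chin = ec, A = 23, sigma = sg)
  expect_equal(coverage(rec(104.85, 10.2, 5), ref_table), 1.0)
  expect_equal(coverage(rec(80, 10.2, 5), ref_table), 0.0)

  ch <- synth_cohort(cohort_spec(n = 20000, seed = 3))
  tab <- build_sizing_table(ch)
  cov <- coverage(ch, tab, rule = "shell_only")
  fit <- fit_normal(ch$eye_to_chin)
  closed <- stats::pnorm(max(tab$shell_brackets$upper), fit$mu, fit$sd) -
    stats::pnorm(min(tab$shell_brackets$lower), fit$mu, fit$sd)
  expect_lt(abs(cov - closed), 0.005)
  # joint eligibility can only remove records relative to shell-only
  expect_lte(coverage(ch, tab), cov)
})

test_that("compare_param_sets recovers shifts and noise scales", {
  set.seed(21)
  a <- data.frame(subject_id = sprintf("s%05d", 1:10000),
                  eye_to_chin = rnorm(10000, 104.85, 6.37),
                  A = rnorm(10000, 23.3, 1),
                  sigma = rnorm(10000, 10.1, 0.68))
  expect_equal(compare_param_sets(a, a)$mean_diff, rep(0, 3))

  shift <- a
  shift$eye_to_chin <- a$eye_to_chin - 2.4
  s <- compare_param_sets(a, shift)
  expect_equal(s$mean_diff[s$parameter == "eye_to_chin"], 2.4)
  expect_equal(s$sd_diff[s$parameter == "eye_to_chin"], 0)
  expect_equal(s$mean_diff_pct[s$parameter == "eye_to_chin"],
               100 * 2.4 / mean(a$eye_to_chin))

  noisy <- a
  noisy$eye_to_chin <- a$eye_to_chin + rnorm(10000, 0, 2.9)
  nz <- compare_param_sets(a, noisy)
  expect_equal(nz$sd_diff[nz$parameter == "eye_to_chin"], 2.9,
               tolerance = 0.05)

  bad <- a[1:10, ]
  bad$subject_id <- paste0("x", bad$subject_id)
  expect_error(compare_param_sets(a[1:10, ], bad), "mismatch")
})

test_that("sizing tables survive CSV and JSON round trips", {
  ch <- synth_cohort(cohort_spec(n = 2000, seed = 8))
  tab <- build_sizing_table(ch)
  td <- withr::local_tempdir()
  p1 <- file.path(td, "tab.csv")
  p2 <- file.path(td, "tab.json")
  write_sizing_table(tab, p1)
  write_sizing_table(tab, p2)
  r1 <- read_sizing_table(p1)
  r2 <- read_sizing_table(p2)
  for (r in list(r1, r2)) {
    expect_equal(r$shell_brackets$lower, tab$shell_brackets$lower,
                 tolerance = 1e-9)
    expect_equal(r$profiles$upper, tab$profiles$upper, tolerance = 1e-9)
  }
})
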