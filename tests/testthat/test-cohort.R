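test_that("allele-burden changes classify by the strict and banded rules", {
  expect_equal(as.character(classify_vaf_change(10, 10)), "stable")
  expect_equal(as.character(classify_vaf_change(5, 3)), "decrease")
  expect_equal(as.character(classify_vaf_change(3, 5)), "increase")
  expect_true(is.na(classify_vaf_change(3, NA)))
  # banded rule absorbs small changes
  expect_equal(as.character(classify_vaf_change(10, 10.4, band = 0.5)),
               "stable")
  expect_equal(as.character(classify_vaf_change(10, 11, band = 0.5)),
               "increase")
  expect_error(classify_vaf_change(1, 2, band = -1), "non-negative")
})

test_that("the published screening flow reproduces the headline percentages", {
  fl <- cohort_flow(copenhagen_counts())
  expect_equal(fl$n_stable, 8)
  expect_equal(fl$pct_nonprogressing_of_undiagnosed, 38)  # 3/8 rounded
  expect_equal(fl$pct_equilibrium_of_reinvited, 15)       # 8/52 rounded
  expect_equal(fl$n_increase, 5)
  expect_equal(fl$n_decrease, 3)
})

test_that("flow summaries reject inconsistent counts and guard divisions", {
  bad <- modifyList(copenhagen_counts(), list(n_reinvited = 70))
  expect_error(cohort_flow(bad), "n_reinvited")
  bad2 <- modifyList(copenhagen_counts(), list(n_diagnosed_at_followup = 30))
  expect_error(cohort_flow(bad2), "exceeds")
  # an all-zero cohort reports missing percentages, not 0/0
  empty <- list(n_screened = 0, n_positive = 0, n_reinvited = 0,
                n_undiagnosed_at_reexam = 0, n_diagnosed_at_followup = 0,
                n_increase = 0, n_decrease = 0)
  fl <- cohort_flow(empty)
  expect_true(is.na(fl$pct_nonprogressing_of_undiagnosed))
  expect_true(is.na(fl$pct_equilibrium_of_reinvited))
})

test_that("table-based flow is invariant to row order and matches counts", {
  pop <- sample_population(vp_population_spec(5, seed = 2))
  coh <- generate_screening_cohort(screening_spec(seed = 9), pop)
  fl <- suppressWarnings(cohort_flow(coh))
  perm <- coh[sample(nrow(coh)), ]
  attr(perm, "n_screened") <- attr(coh, "n_screened")
  fl_perm <- suppressWarnings(cohort_flow(perm))
  expect_equal(fl, fl_perm)
  expect_equal(fl$n_positive, nrow(coh))
  expect_equal(fl$n_reinvited, sum(coh$survived))
})

test_that("prevalence slope fitting is exact, end-robust and equivariant", {
  # collinear points recover the generating slope exactly
  tab <- generate_prevalence_table(slope = 0.1, intercept = -2,
                                   exact = TRUE)
  fit <- fit_prevalence_slope(tab)
  expect_equal(fit$slope_per_year, 0.1, tolerance = 1e-10)
  expect_equal(fit$slope_per_decade, 1, tolerance = 1e-10)

  # outlier end bins pull the full fit away; dropping them restores the
  # interior trend
  tab2 <- tab
  tab2$n_positive[1] <- tab2$n_positive[1] * 8
  tab2$n_positive[nrow(tab2)] <- 0
  slope_all <- fit_prevalence_slope(tab2, drop_first_last = FALSE)$slope_per_year
  slope_int <- fit_prevalence_slope(tab2, drop_first_last = TRUE)$slope_per_year
  expect_equal(slope_int, 0.1, tolerance = 1e-10)
  expect_gt(abs(slope_all - 0.1), abs(slope_int - 0.1))

  # scaling all prevalences by k scales the slope by k
  tab3 <- tab
  tab3$n_positive <- tab3$n_positive * 3
  expect_equal(fit_prevalence_slope(tab3)$slope_per_year, 0.3,
               tolerance = 1e-10)

  # too few bins after dropping
  expect_error(fit_prevalence_slope(tab[1:4, ]), "at least 3")
})

test_that("tidy and glance expose the prevalence fit in broom style", {
  fit <- fit_prevalence_slope(generate_prevalence_table(seed = 4))
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "age_mid"))
  expect_true(all(c("estimate", "std.error", "p.value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$slope_per_year, fit$slope_per_year)
  expect_equal(gl$n_bins_used, 4)
})

test_that("model-epidemiology comparison reports slopes, ratio and agreement", {
  esc <- escape_curve(default_params())
  # uncalibrated: ratio suppressed
  cmp0 <- suppressWarnings(compare_model_to_epidemiology(esc, 0.1))
  expect_true(is.na(cmp0$ratio))
  # calibrated curves: build synthetic escape objects around known slopes
  esc2 <- esc
  esc2$calibrated <- TRUE
  esc2$slope <- 0.2
  cmp <- compare_model_to_epidemiology(esc2, 0.1)
  expect_equal(cmp$ratio, 2)
  expect_true(cmp$within_factor)
  esc2$slope <- 0.1
  expect_equal(compare_model_to_epidemiology(esc2, 0.1)$ratio, 1)
  # zero prevalence slope: ratio undefined, not an error
  expect_true(is.na(compare_model_to_epidemiology(esc2, 0)$ratio))
})

test_that("cohort tables round-trip through CSV with the screened total", {
  pop <- sample_population(vp_population_spec(4, seed = 3))
  coh <- generate_screening_cohort(screening_spec(seed = 10), pop)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(coh, f)
  back <- read_cohort_csv(f)
  expect_equal(attr(back, "n_screened"), attr(coh, "n_screened"))
  expect_equal(as.data.frame(back), as.data.frame(coh), tolerance = 1e-8)
  expect_equal(suppressWarnings(cohort_flow(back)),
               suppressWarnings(cohort_flow(coh)))
})
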