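test_that("generators are pure functions of their spec and seed", {
  spec <- vp_population_spec(30, dispersion = 0.05, seed = 42)
  expect_identical(sample_population(spec), sample_population(spec))
  pop <- sample_population(spec)
  sc <- screening_spec(seed = 8)
  expect_identical(generate_screening_cohort(sc, pop),
                   generate_screening_cohort(sc, pop))
  expect_identical(generate_prevalence_table(seed = 6),
                   generate_prevalence_table(seed = 6))
  # the generators do not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(sample_population(spec)); after <- runif(1)
  expect_identical(before, after)
})

test_that("zero dispersion collapses the population onto the base set", {
  pop <- sample_population(vp_population_spec(8, dispersion = 0,
                                              ages = rep(60, 8), seed = 1))
  base <- default_params()
  expect_true(all(pop$K_x == base$K_x))
  expect_true(all(pop$beta_y == base$beta_y))
  expect_equal(pop$alpha, rep(alpha_at_age(age_map(), 60), 8))
  # a row rebuilds into a valid parameter object
  expect_s3_class(params_from_row(pop[1, ]), "ric_params")
})

test_that("population subtypes shift from dormant- to fatal-dominated with age", {
  young <- sample_population(vp_population_spec(
    40, dispersion = 0.002, ages = rep(16, 40), seed = 21))
  old <- sample_population(vp_population_spec(
    40, dispersion = 0.002, ages = rep(84, 40), seed = 22))
  subtype_of <- function(pop) {
    vapply(seq_len(nrow(pop)), function(i) {
      as.character(classify_subtype(params_from_row(pop[i, ])))
    }, character(1))
  }
  sy <- subtype_of(young)
  so <- subtype_of(old)
  expect_gt(mean(sy == "D"), 0.5)
  expect_gt(mean(so == "F"), 0.5)
  expect_gt(mean(so == "F"), mean(sy == "F"))
  expect_gt(mean(sy == "D"), mean(so == "D"))
})

test_that("noise-free equilibrium cohorts are classified entirely stable", {
  pop <- sample_population(vp_population_spec(5, dispersion = 0, seed = 4))
  sc <- screening_spec(noise_sd = 0, p_equilibrium = 1, death_prob = 0,
                       seed = 12)
  coh <- generate_screening_cohort(sc, pop)
  chg <- classify_vaf_change(coh$vaf_baseline, coh$vaf_followup, band = 0.5)
  expect_true(all(chg == "stable"))
})

test_that("a population in the fatal basin yields mostly increasing burdens", {
  # monostable-fatal patients: every progressor climbs toward the fatal
  # branch over the follow-up interval
  pop <- sample_population(vp_population_spec(
    5, dispersion = 0, ages = rep(85, 5), seed = 5))  # alpha below window
  expect_equal(as.character(classify_subtype(params_from_row(pop[1, ]))),
               "F")
  sc <- screening_spec(noise_sd = 0, p_equilibrium = 0, death_prob = 0,
                       seed = 13)
  coh <- generate_screening_cohort(sc, pop)
  chg <- classify_vaf_change(coh$vaf_baseline, coh$vaf_followup)
  expect_gt(mean(chg == "increase"), 0.9)
})

test_that("cohort generation recovers the configured equilibrium fraction", {
  pop <- sample_population(vp_population_spec(3, dispersion = 0, seed = 6))
  p_eq <- 8 / 52
  stable <- 0; reinvited <- 0
  for (s in 1:100) {
    coh <- generate_screening_cohort(screening_spec(seed = 1000 + s), pop)
    fl <- suppressWarnings(cohort_flow(coh))
    stable <- stable + fl$n_stable
    reinvited <- reinvited + fl$n_reinvited
  }
  se <- sqrt(p_eq * (1 - p_eq) / reinvited)
  expect_lt(abs(stable / reinvited - p_eq), 3 * se)
})

test_that("prevalence tables respect their linear law and recover the slope", {
  expect_error(generate_prevalence_table(slope = -1, intercept = 0),
               "outside")
  # exact mode is the noiseless large-sample limit
  fit0 <- fit_prevalence_slope(generate_prevalence_table(exact = TRUE))
  expect_equal(fit0$slope_per_year, 0.1, tolerance = 1e-10)
  # binomial sampling: the mean recovered slope over 100 replicates is
  # within two standard errors of the generating slope
  slopes <- vapply(1:100, function(s) {
    tab <- generate_prevalence_table(slope = 0.1, intercept = -2,
                                     n_per_bin = 1000, seed = s)
    fit_prevalence_slope(tab)$slope_per_year
  }, numeric(1))
  se_mean <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 0.1), 2 * se_mean)
})

test_that("generated tables pass the consuming validators after CSV round-trip", {
  pop <- sample_population(vp_population_spec(4, dispersion = 0.01, seed = 7))
  coh <- generate_screening_cohort(screening_spec(seed = 14), pop)
  expect_true(all(coh$vaf_baseline >= 0 & coh$vaf_baseline <= 100))
  fu <- coh$vaf_followup[!is.na(coh$vaf_followup)]
  expect_true(all(fu >= 0 & fu <= 100))
  expect_true(all(is.na(coh$vaf_followup[!coh$survived])))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(coh, f)
  expect_s3_class(suppressWarnings(cohort_flow(read_cohort_csv(f))),
                  "tbl_df")
})
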