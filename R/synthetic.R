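# Synthetic-data generators: virtual-patient populations, screening
# cohorts with baseline/follow-up allele burden, and prevalence-by-age
# tables. All generators are pure functions of (spec, seed).

.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Virtual-patient population specification
#'
#' Each physiological parameter is drawn log-normally around the base
#' parameter set (median = base value, log-sd = `dispersion`); apoptosis
#' probabilities are resampled until they stay in (0, 1). Each subject gets
#' an age and the age-mapped naive T-cell production rate
#' `alpha = alpha_at_age(agemap, age)`.
#'
#' @param n_subjects Number of virtual patients.
#' @param dispersion Log-scale standard deviation of the parameter
#'   distributions (0 = every subject shares the base set).
#' @param agemap A [age_map()] object.
#' @param ages Either a length-2 range (uniform sampling) or a vector of
#'   length `n_subjects` of fixed ages.
#' @param base_params Base [ric_params] set (median of the population).
#' @param seed Integer seed; the generator is deterministic given the spec.
#' @return An object of class `ric_population_spec`.
#' @export
vp_population_spec <- function(n_subjects, dispersion = 0,
                               agemap = age_map(), ages = c(40, 80),
                               base_params = default_params(), seed = 1) {
  stopifnot(inherits(agemap, "ric_agemap"),
            inherits(base_params, "ric_params"))
  if (n_subjects < 1) abort("n_subjects must be at least 1")
  if (dispersion < 0) abort("dispersion must be non-negative")
  if (!(length(ages) == 2 || length(ages) == n_subjects)) {
    abort("ages must be a length-2 range or one age per subject")
  }
  structure(list(n_subjects = n_subjects, dispersion = dispersion,
                 agemap = agemap, ages = ages, base_params = base_params,
                 seed = seed),
            class = "ric_population_spec")
}

#' Sample a virtual-patient population
#'
#' @param spec A [vp_population_spec()] object.
#' @return A tibble with one row per subject: `id`, `age`, the fourteen
#'   parameter columns (with `alpha` set from the age map).
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "ric_population_spec"))
  base <- unclass(spec$base_params)
  fields <- setdiff(names(base), "alpha")
  .with_seed(spec$seed, {
    ages <- if (length(spec$ages) == 2) {
      stats::runif(spec$n_subjects, spec$ages[1], spec$ages[2])
    } else spec$ages
    draws <- purrr::map(fields, function(f) {
      v <- base[[f]] *
        exp(stats::rnorm(spec$n_subjects, 0, spec$dispersion))
      if (f %in% c("p_x", "p_y")) {
        bad <- which(v >= 1)
        while (length(bad)) {
          v[bad] <- base[[f]] *
            exp(stats::rnorm(length(bad), 0, spec$dispersion))
          bad <- bad[v[bad] >= 1]
        }
      }
      if (f %in% c("K_x", "K_y")) v <- pmax(v, 1)
      v
    })
    names(draws) <- fields
    out <- tibble(id = seq_len(spec$n_subjects), age = ages,
                  alpha = alpha_at_age(spec$agemap, ages))
    dplyr::bind_cols(out, tibble::as_tibble(draws))
  })
}

#' Rebuild a parameter object from one population row
#'
#' @param row One row of a [sample_population()] tibble.
#' @return A [ric_params] object.
#' @export
params_from_row <- function(row) {
  ric_params(a_x = row$a_x, a_y = row$a_y, K_x = row$K_x, K_y = row$K_y,
             alpha = row$alpha, epsilon = row$epsilon,
             beta_x = row$beta_x, beta_y = row$beta_y,
             p_x = row$p_x, p_y = row$p_y, d_x = row$d_x, d_y = row$d_y,
             r_x = row$r_x, r_y = row$r_y)
}

#' Screening-cohort specification
#'
#' Emulates the structure of a population screening with follow-up: a
#' screened population, a small mutation-positive fraction, deaths before
#' re-invitation, interim diagnoses, diagnoses at the re-examination, and a
#' final undiagnosed group in temporary dormant equilibrium. The default
#' probabilities are the published flow proportions (63/49,488 positive,
#' 11/63 dead before follow-up, 8/52 of survivors in equilibrium, 26/44 of
#' progressing survivors diagnosed in the interim).
#'
#' @param n_screened Number of citizens screened.
#' @param positivity_rate Probability a screened citizen is
#'   mutation-positive.
#' @param death_prob Probability a positive subject dies before follow-up.
#' @param p_equilibrium Probability a surviving positive subject is in the
#'   dormant equilibrium (the configured stable fraction of the
#'   re-invited).
#' @param p_interim_given_progressing Probability a progressing survivor is
#'   diagnosed between screening and re-examination.
#' @param followup_years Years between baseline and follow-up (dimensionless
#'   model time is interpreted as years here, `a_x = 1/year`).
#' @param noise_sd Gaussian measurement noise on the percent VAF scale.
#' @param vaf_scale Linear map from normalized burden X to percent VAF
#'   (default 100 * X, capped at 100).
#' @param chip_vaf_threshold Optional allele-burden positivity gate in
#'   percent (e.g. 2); `NULL` disables the gate.
#' @param seed Integer seed.
#' @return An object of class `ric_screening_spec`.
#' @export
screening_spec <- function(n_screened = 49488,
                           positivity_rate = 63 / 49488,
                           death_prob = 11 / 63,
                           p_equilibrium = 8 / 52,
                           p_interim_given_progressing = 26 / 44,
                           followup_years = 6,
                           noise_sd = 0.5,
                           vaf_scale = 100,
                           chip_vaf_threshold = NULL,
                           seed = 1) {
  probs <- c(positivity_rate, death_prob, p_equilibrium,
             p_interim_given_progressing)
  if (any(probs < 0) || any(probs > 1)) abort("probabilities must be in [0, 1]")
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  structure(list(n_screened = n_screened, positivity_rate = positivity_rate,
                 death_prob = death_prob, p_equilibrium = p_equilibrium,
                 p_interim_given_progressing = p_interim_given_progressing,
                 followup_years = followup_years, noise_sd = noise_sd,
                 vaf_scale = vaf_scale,
                 chip_vaf_threshold = chip_vaf_threshold, seed = seed),
            class = "ric_screening_spec")
}

# model-implied baseline/follow-up normalized cancer burdens for one
# parameter set: equilibrium subjects sit at the dormant state; progressing
# subjects start just outside the dormant basin (displaced across the
# saddle) and move toward the fatal branch over the follow-up interval.
.trajectory_anchors <- function(params, followup_years) {
  cl <- cluster_params(params)
  st <- find_steady_states(cl)
  dorm <- dplyr::filter(st, .data$role == "dormant",
                        .data$stability == "stable")
  thr <- dplyr::filter(st, .data$role == "threshold")
  fatal <- dplyr::filter(st, .data$role == "fatal",
                         .data$stability == "stable")
  X_eq <- if (nrow(dorm)) dorm$X[1] else if (nrow(fatal)) fatal$X[1] else 0
  if (nrow(thr)) {
    start <- c(thr$X[1] * 1.05, thr$Y[1] * 1.05)
  } else if (nrow(fatal)) {
    start <- c(fatal$X[1] * 0.25, fatal$Y[1] * 0.25)
  } else {
    start <- c(X_eq, X_eq)
  }
  tr <- simulate_ric(cl, start[1], start[2], t_end = max(followup_years, 1),
                     n = 50)
  list(X_eq = X_eq, X_prog0 = tr$X[1], X_prog1 = tr$X[nrow(tr)])
}

#' Generate a synthetic screening cohort
#'
#' Draws the cohort flow hierarchically (positivity, survival, equilibrium
#' versus progression, interim versus follow-up diagnosis) and fills in
#' baseline/follow-up allele burdens from the model: equilibrium subjects
#' sit at their dormant steady state, progressing subjects follow a
#' trajectory from just beyond the threshold state toward the fatal branch
#' over the follow-up interval. Gaussian measurement noise is added on the
#' percent scale and truncated to \[0, 100\].
#'
#' @param spec A [screening_spec()] object.
#' @param population A [sample_population()] tibble; positives draw their
#'   parameters from its rows (recycled as needed).
#' @return A cohort tibble (one row per mutation-positive subject) with
#'   columns `id`, `age`, `vaf_baseline`, `vaf_followup`, `survived`,
#'   `diagnosed_interim`, `diagnosed_at_followup` and attribute
#'   `n_screened`.
#' @export
generate_screening_cohort <- function(spec, population) {
  stopifnot(inherits(spec, "ric_screening_spec"))
  .with_seed(spec$seed, {
    n_pos <- stats::rbinom(1, spec$n_screened, spec$positivity_rate)
    if (n_pos == 0) {
      out <- tibble(id = integer(0), age = numeric(0),
                    vaf_baseline = numeric(0), vaf_followup = numeric(0),
                    survived = logical(0), diagnosed_interim = logical(0),
                    diagnosed_at_followup = logical(0))
      attr(out, "n_screened") <- spec$n_screened
      return(out)
    }
    rows <- population[rep_len(seq_len(nrow(population)), n_pos), ]
    survived <- stats::runif(n_pos) >= spec$death_prob
    equil <- stats::runif(n_pos) < spec$p_equilibrium
    interim <- !equil & (stats::runif(n_pos) <
                           spec$p_interim_given_progressing)
    # anchors per unique parameter set (population rows are often shared)
    key <- do.call(paste, c(rows[, setdiff(names(rows), c("id", "age"))],
                            sep = "|"))
    uk <- !duplicated(key)
    anchors <- purrr::map(which(uk), function(i) {
      .trajectory_anchors(params_from_row(rows[i, ]), spec$followup_years)
    })
    names(anchors) <- key[uk]
    X0 <- vapply(seq_len(n_pos), function(i) {
      a <- anchors[[key[i]]]
      if (equil[i]) a$X_eq else a$X_prog0
    }, numeric(1))
    X1 <- vapply(seq_len(n_pos), function(i) {
      a <- anchors[[key[i]]]
      if (equil[i]) a$X_eq else a$X_prog1
    }, numeric(1))
    to_vaf <- function(X, noise) {
      pmin(pmax(pmin(spec$vaf_scale * X, 100) + noise, 0), 100)
    }
    vaf0 <- to_vaf(X0, stats::rnorm(n_pos, 0, spec$noise_sd))
    vaf1 <- to_vaf(X1, stats::rnorm(n_pos, 0, spec$noise_sd))
    vaf1[!survived] <- NA_real_
    diagnosed_at_followup <- survived & !interim & !equil
    out <- tibble(
      id = seq_len(n_pos),
      age = rows$age,
      vaf_baseline = vaf0,
      vaf_followup = vaf1,
      survived = survived,
      diagnosed_interim = interim & survived,
      diagnosed_at_followup = diagnosed_at_followup
    )
    if (!is.null(spec$chip_vaf_threshold)) {
      out <- out[out$vaf_baseline >= spec$chip_vaf_threshold, ]
      out$id <- seq_len(nrow(out))
    }
    attr(out, "n_screened") <- spec$n_screened
    out
  })
}

#' Generate a synthetic prevalence-by-age table
#'
#' Positive counts are binomial draws around a linear prevalence-age law
#' evaluated at bin midpoints. In `exact` mode the expected (possibly
#' non-integer) counts are used, giving the noiseless large-sample limit.
#'
#' @param slope Prevalence slope in percent per year.
#' @param intercept Prevalence (percent) extrapolated to age 0.
#' @param breaks Increasing age-bin edges (default decades 30 to 90).
#' @param n_per_bin Citizens screened per bin (scalar or per-bin vector).
#' @param seed Integer seed.
#' @param exact Use expected counts instead of binomial draws.
#' @return A prevalence tibble: `age_lo`, `age_hi`, `n_screened`,
#'   `n_positive`.
#' @export
generate_prevalence_table <- function(slope = 0.1, intercept = -2,
                                      breaks = seq(30, 90, by = 10),
                                      n_per_bin = 1000, seed = 1,
                                      exact = FALSE) {
  if (length(breaks) < 3 || is.unsorted(breaks, strictly = TRUE)) {
    abort("breaks must be at least 3 increasing edges")
  }
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1]
  mid <- (lo + hi) / 2
  prev <- intercept + slope * mid
  if (any(prev < 0) || any(prev > 100)) {
    abort("slope/intercept imply prevalence outside [0, 100] on these bins")
  }
  n <- rep_len(n_per_bin, length(mid))
  pos <- if (exact) n * prev / 100 else {
    .with_seed(seed, stats::rbinom(length(mid), n, prev / 100))
  }
  tibble(age_lo = lo, age_hi = hi, n_screened = n, n_positive = pos)
}
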