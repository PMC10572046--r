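# Alpha scans, saddle-node detection, the age proxy and the escape curve.

.clusters_at_alpha <- function(params, alpha) {
  cluster_params(with_alpha(params, alpha))
}

.interior_branch <- function(states, alpha) {
  int <- dplyr::filter(states, .data$role %in%
                         c("dormant", "fatal", "threshold"))
  if (nrow(int) == 0) return(NULL)
  dplyr::mutate(int[, c("X", "Y", "stability", "role")],
                alpha = alpha, .before = 1)
}

# Newton polish of a saddle-node point on the extended system
# (f, g, det J)(X, Y, alpha) = 0, seeded from the near-merged pair.
.polish_sn <- function(params, X0, Y0, a0) {
  Ffun <- function(v) {
    cl <- .clusters_at_alpha(params, v[3])
    fg <- .reduced_fg(v[1], v[2], cl)
    j <- .jac_num(v[1], v[2], cl)
    c(fg$f, fg$g, j$j11 * j$j22 - j$j12 * j$j21)
  }
  v <- c(X0, Y0, a0)
  for (it in 1:40) {
    Fv <- Ffun(v)
    J <- matrix(0, 3, 3)
    for (k in 1:3) {
      h <- 1e-7 * max(abs(v[k]), 1e-4)
      vp <- v; vm <- v
      vp[k] <- v[k] + h; vm[k] <- v[k] - h
      J[, k] <- (Ffun(vp) - Ffun(vm)) / (2 * h)
    }
    step <- tryCatch(solve(J, Fv), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    v <- v - step
    if (max(abs(step)) < 1e-12) break
  }
  if (max(abs(Ffun(v))) > 1e-6 || v[3] <= 0 ||
      any(v[1:2] < 0) || any(v[1:2] > 1)) return(NULL)
  v
}

#' Scan the naive T-cell production rate for saddle-node bifurcations
#'
#' For each `alpha` on the grid the clusters are recomputed (only A1 and B1
#' change, both proportional to `alpha`), all interior steady states are
#' located and classified, and branches are assembled. A change in the
#' number of interior stable states between adjacent grid points brackets a
#' saddle-node; the bracket is refined by bisection on that count to
#' `alpha_tol`, then polished by Newton iteration on the extended system
#' (equilibrium + zero Jacobian determinant), which pins the merge point to
#' machine precision.
#'
#' @param params A [ric_params] object (all parameters except `alpha` are
#'   held fixed).
#' @param alphas Positive, sorted scan grid.
#' @param alpha_tol Bisection tolerance on the bifurcation value.
#' @return An object of class `ric_bifurcation`: a list with `branches`
#'   (tibble: `alpha`, `X`, `Y`, `stability`, `role`), `sn_points` (tibble:
#'   `alpha`, `type`, `X`, `Y`, `eig_min`) and `alphas`.
#' @export
scan_alpha <- function(params, alphas, alpha_tol = 1e-3) {
  stopifnot(inherits(params, "ric_params"))
  if (is.unsorted(alphas) || any(alphas <= 0)) {
    abort("alphas must be a positive increasing grid")
  }
  per_alpha <- purrr::map(alphas, function(a) {
    st <- find_steady_states(.clusters_at_alpha(params, a))
    list(states = st,
         n_stable = sum(st$stability == "stable" &
                          st$role %in% c("dormant", "fatal")))
  })
  branches <- purrr::map_dfr(seq_along(alphas), function(i) {
    .interior_branch(per_alpha[[i]]$states, alphas[i])
  })
  counts <- vapply(per_alpha, `[[`, numeric(1), "n_stable")
  count_at <- function(a) {
    st <- find_steady_states(.clusters_at_alpha(params, a))
    sum(st$stability == "stable" & st$role %in% c("dormant", "fatal"))
  }
  sn <- NULL
  for (i in which(diff(counts) != 0)) {
    lo <- alphas[i]; hi <- alphas[i + 1]
    if (abs(counts[i + 1] - counts[i]) > 1) {
      warn(sprintf(paste0("stable-state count jumps by more than one ",
                          "between alpha = %g and %g; refine the grid"),
                   lo, hi))
    }
    c_lo <- counts[i]
    while (hi - lo > alpha_tol) {
      mid <- (lo + hi) / 2
      if (count_at(mid) == c_lo) lo <- mid else hi <- mid
    }
    # the bistable side of the bracket carries the merging pair
    a_bi <- if (counts[i] > counts[i + 1]) lo else hi
    st <- find_steady_states(.clusters_at_alpha(params, a_bi))
    thr <- dplyr::filter(st, .data$role == "threshold")
    stb <- dplyr::filter(st, .data$stability == "stable",
                         .data$role %in% c("dormant", "fatal"))
    if (nrow(thr) == 0 || nrow(stb) == 0) next
    d2 <- (stb$X - thr$X[1])^2 + (stb$Y - thr$Y[1])^2
    mate <- stb[which.min(d2), ]
    seed <- c((mate$X + thr$X[1]) / 2, (mate$Y + thr$Y[1]) / 2,
              (lo + hi) / 2)
    pol <- .polish_sn(params, seed[1], seed[2], seed[3])
    a_sn <- if (is.null(pol)) (lo + hi) / 2 else pol[3]
    loc <- if (is.null(pol)) seed[1:2] else pol[1:2]
    cl_sn <- .clusters_at_alpha(params, a_sn)
    ev <- .classify_jacobian(loc[1], loc[2], cl_sn)$ev
    sn <- dplyr::bind_rows(sn, tibble(
      alpha = a_sn,
      type = paste0(mate$role, "-threshold"),
      X = loc[1], Y = loc[2],
      eig_min = min(abs(Re(ev)))
    ))
  }
  structure(list(branches = branches,
                 sn_points = sn %||% tibble(alpha = numeric(0),
                                            type = character(0),
                                            X = numeric(0), Y = numeric(0),
                                            eig_min = numeric(0)),
                 alphas = alphas),
            class = "ric_bifurcation")
}

#' @export
print.ric_bifurcation <- function(x, ...) {
  cat(sprintf("<ric_bifurcation> %d alpha values, %d saddle-node point(s)\n",
              length(x$alphas), nrow(x$sn_points)))
  if (nrow(x$sn_points)) print(x$sn_points)
  invisible(x)
}

#' Linear age map for the naive T-cell production rate
#'
#' Immuno-aging is represented by a linear decline of the baseline
#' production rate: `alpha(age) = alpha_at_age0 + slope * age`, clipped at
#' zero. The default maps age 20 to `alpha = 100` and age 80 to
#' `alpha = 16`, so the dormant-to-risk and risk-to-fatal transitions fall
#' at plausible screening-cohort ages.
#'
#' @param alpha_at_age0 Production rate extrapolated to age 0.
#' @param slope Change per year of age (must be negative).
#' @return An object of class `ric_agemap`.
#' @export
age_map <- function(alpha_at_age0 = 128, slope = -1.4) {
  if (!is.numeric(slope) || slope >= 0) abort("agemap slope must be negative")
  structure(list(alpha_at_age0 = alpha_at_age0, slope = slope),
            class = "ric_agemap")
}

#' @rdname age_map
#' @param agemap A `ric_agemap` object.
#' @param age Ages in years (vectorized).
#' @export
alpha_at_age <- function(agemap, age) {
  stopifnot(inherits(agemap, "ric_agemap"))
  pmax(0, agemap$alpha_at_age0 + agemap$slope * age)
}

#' Bifurcation diagram as a function of age
#'
#' Composes an alpha scan with the age map, reporting equilibrium branches
#' per age and the ages at which the subject's subtype changes (D to R at
#' the upper saddle-node, R to F at the lower one, for a declining alpha).
#'
#' @param params A [ric_params] object.
#' @param agemap A [age_map()] object.
#' @param ages Increasing age grid in years.
#' @inheritParams scan_alpha
#' @return An object of class `ric_age_diagram`: list with `branches`
#'   (tibble keyed by `age` and `alpha`), `transitions` (tibble: `age`,
#'   `alpha`, `type`, `transition`) and `agemap`.
#' @export
diagram_vs_age <- function(params, agemap, ages, alpha_tol = 1e-3) {
  stopifnot(inherits(agemap, "ric_agemap"))
  al <- alpha_at_age(agemap, ages)
  if (any(agemap$alpha_at_age0 + agemap$slope * ages <= 0)) {
    warn("alpha(age) clipped at zero within the age grid")
  }
  al_eff <- pmax(al, 1e-8)
  scan <- scan_alpha(params, sort(unique(al_eff)), alpha_tol = alpha_tol)
  branches <- purrr::map_dfr(seq_along(ages), function(i) {
    b <- dplyr::filter(scan$branches, abs(.data$alpha - al_eff[i]) < 1e-12)
    if (nrow(b)) dplyr::mutate(b, age = ages[i], .before = 1)
  })
  transitions <- dplyr::mutate(
    scan$sn_points,
    age = (.data$alpha - agemap$alpha_at_age0) / agemap$slope,
    transition = ifelse(.data$type == "fatal-threshold", "D->R", "R->F")
  )[, c("age", "alpha", "type", "transition")]
  transitions <- dplyr::arrange(transitions, .data$age)
  structure(list(branches = branches, transitions = transitions,
                 agemap = agemap),
            class = "ric_age_diagram")
}

#' Escape-probability curve over age
#'
#' Inside the bistable window the dormant state is protected by the
#' threshold (saddle) state lying above it on the infection axis. The
#' vertical gap between the threshold branch and the dormant branch,
#' `distance = Y_threshold - Y_dormant`, is the infection perturbation
#' needed for disease escape; the escape probability under a continuous
#' infection load is taken inversely proportional to it,
#' `probability = c / distance`. Outside the bistable window the distance
#' is undefined (`NA`). A linear fit of probability against age is
#' restricted by default to ages at least 20 years above the lower
#' (risk-to-fatal) transition, because the inverse distance diverges like
#' an inverse square root as the saddle-node is approached and the linear
#' description only holds in the interior of the window.
#'
#' @param params A [ric_params] object.
#' @param agemap A [age_map()] object.
#' @param ages Age grid in years (default 21 to 79, one-year steps).
#' @param c Proportionality constant. The default 1 reports probability in
#'   arbitrary units; supply a calibrated value (and set
#'   `calibrated = TRUE`) to report percent per year.
#' @param calibrated Whether `c` converts the probability to percent.
#' @param fit_ages Age range used for the linear fit.
#' @return An object of class `ric_escape`: list with `curve` (tibble:
#'   `age`, `alpha`, `distance`, `probability`), `fit` (an `lm`), `slope`,
#'   `r_squared`, `calibrated`.
#' @export
escape_curve <- function(params, agemap = age_map(), ages = 21:79,
                         c = 1, calibrated = FALSE, fit_ages = c(21, 60)) {
  stopifnot(inherits(params, "ric_params"), inherits(agemap, "ric_agemap"))
  al <- alpha_at_age(agemap, ages)
  rows <- purrr::map_dfr(seq_along(ages), function(i) {
    st <- find_steady_states(.clusters_at_alpha(params, al[i]))
    dorm <- dplyr::filter(st, .data$role == "dormant",
                          .data$stability == "stable")
    thr <- dplyr::filter(st, .data$role == "threshold")
    n_stab <- sum(st$stability == "stable" &
                    st$role %in% c("dormant", "fatal"))
    d <- if (n_stab == 2 && nrow(thr) == 1 && nrow(dorm) == 1) {
      thr$Y - dorm$Y
    } else NA_real_
    tibble(age = ages[i], alpha = al[i], distance = d)
  })
  rows$probability <- c / rows$distance
  sel <- is.finite(rows$probability) &
    rows$age >= fit_ages[1] & rows$age <= fit_ages[2]
  fit <- NULL; slope <- NA_real_; r2 <- NA_real_
  if (sum(sel) >= 3) {
    fit <- stats::lm(probability ~ age, data = rows[sel, ])
    slope <- unname(stats::coef(fit)[2])
    r2 <- summary(fit)$r.squared
  }
  structure(list(curve = rows, fit = fit, slope = slope, r_squared = r2,
                 calibrated = isTRUE(calibrated)),
            class = "ric_escape")
}

#' @export
print.ric_escape <- function(x, ...) {
  cat(sprintf(
    "<ric_escape> %d ages, slope %.4g %s/year (R^2 = %.3f)\n",
    nrow(x$curve), x$slope,
    if (x$calibrated) "%" else "a.u.", x$r_squared))
  invisible(x)
}
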