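# On-off naive T-cell therapy: the non-autonomous system with time-varying
# alpha(t) under a hysteresis controller keyed to the cancer burden.

#' Treatment schedule for naive T-cell therapy
#'
#' Between treatments `alpha` decays exponentially toward `alpha_floor` at
#' `off_rate`; during treatment it saturates toward `alpha_ceiling` as one
#' minus a decaying exponential at `on_rate`. Treatment switches on when
#' the normalized cancer burden X rises through `threshold_on` and off when
#' it falls through `threshold_off`; the gap between the two thresholds is
#' the hysteresis that prevents chattering. The controller thresholds are
#' modelling choices, not literature values.
#'
#' @param alpha_floor,alpha_ceiling Bounds of the production rate.
#' @param off_rate,on_rate Exponential rates (per dimensionless time).
#' @param threshold_on,threshold_off Cancer-burden switch levels, with
#'   `threshold_off < threshold_on`.
#' @return An object of class `ric_schedule`.
#' @export
treatment_schedule <- function(alpha_floor = 0.15, alpha_ceiling = 100,
                               off_rate = 4, on_rate = 3,
                               threshold_on = 0.5, threshold_off = 0.1) {
  if (alpha_floor >= alpha_ceiling) abort("alpha_floor must be < alpha_ceiling")
  if (off_rate <= 0 || on_rate <= 0) abort("rates must be positive")
  if (!(threshold_off < threshold_on)) {
    abort("hysteresis requires threshold_off < threshold_on")
  }
  structure(list(alpha_floor = alpha_floor, alpha_ceiling = alpha_ceiling,
                 off_rate = off_rate, on_rate = on_rate,
                 threshold_on = threshold_on, threshold_off = threshold_off),
            class = "ric_schedule")
}

#' Simulate on-off naive T-cell therapy
#'
#' Integrates the dimensionless disease dynamics with the immune-response
#' clusters recomputed from the instantaneous `alpha(t)` (both are
#' proportional to it) while `alpha` follows the schedule's exponential
#' laws. Switching is event-based: each phase is integrated with a root
#' function on the active threshold and the integration restarts at the
#' exact crossing, so toggle times are sharp and the on/off flag changes at
#' most once per crossing.
#'
#' @param params A [ric_params] object; its `alpha` is the initial value.
#' @param schedule A [treatment_schedule()] object.
#' @param X0,Y0 Non-negative initial burdens.
#' @param t_end Horizon (dimensionless time).
#' @param dt Output sampling step.
#' @return An object of class `ric_treatment`: tibble with columns `t`,
#'   `X`, `Y`, `alpha`, `treatment_on`.
#' @export
simulate_treated <- function(params, schedule, X0, Y0, t_end, dt = 0.05) {
  stopifnot(inherits(params, "ric_params"),
            inherits(schedule, "ric_schedule"))
  if (X0 < 0 || Y0 < 0) abort("initial state must be non-negative")
  base <- cluster_params(with_alpha(params, 1))
  a1u <- base$A1; b1u <- base$B1
  sc <- schedule
  rhs_phase <- function(on) {
    function(t, s, p) {
      cl <- base
      cl$A1 <- a1u * s[3]; cl$B1 <- b1u * s[3]
      d <- .rhs_num(s[1], s[2], cl)
      dal <- if (on) sc$on_rate * (sc$alpha_ceiling - s[3])
             else -sc$off_rate * (s[3] - sc$alpha_floor)
      list(c(d$dX, d$dY, dal))
    }
  }
  on <- X0 >= sc$threshold_on
  state <- c(X = X0, Y = Y0, alpha = params$alpha)
  t_cur <- 0
  out <- list(tibble(t = 0, X = X0, Y = Y0, alpha = params$alpha,
                     treatment_on = on))
  for (k in 1:1000) {
    if (t_cur >= t_end) break
    thr <- if (on) sc$threshold_off else sc$threshold_on
    rootf <- function(t, s, p) s[1] - thr
    times <- unique(c(seq(t_cur, t_end, by = dt), t_end))
    if (length(times) < 2) times <- c(t_cur, t_end)
    sol <- deSolve::lsodar(state, times, rhs_phase(on), parms = NULL,
                           rtol = 1e-8, atol = 1e-10, rootfunc = rootf)
    seg <- tibble(t = sol[-1, 1], X = sol[-1, 2], Y = sol[-1, 3],
                  alpha = sol[-1, 4], treatment_on = on)
    out[[length(out) + 1]] <- seg
    t_reached <- sol[nrow(sol), 1]
    state <- sol[nrow(sol), 2:4]
    root_hit <- !is.null(attributes(sol)$troot) &&
      length(attributes(sol)$troot) > 0
    if (!root_hit || t_reached >= t_end - 1e-12) break
    # crossing direction decides whether the phase actually toggles
    d <- rhs_phase(on)(t_reached, state, NULL)[[1]]
    if ((!on && d[1] > 0) || (on && d[1] < 0)) {
      on <- !on
      t_cur <- t_reached + 1e-9
    } else {
      # grazing contact: step past the root without switching
      t_step <- min(t_reached + dt, t_end)
      sol2 <- deSolve::lsoda(state, c(t_reached, t_step), rhs_phase(on),
                             parms = NULL, rtol = 1e-8, atol = 1e-10)
      state <- sol2[nrow(sol2), 2:4]
      out[[length(out) + 1]] <- tibble(t = t_step, X = state[1],
                                       Y = state[2], alpha = state[3],
                                       treatment_on = on)
      t_cur <- t_step
    }
  }
  res <- dplyr::bind_rows(out)
  structure(res, class = c("ric_treatment", class(res)))
}

#' Displace a disease state
#'
#' Applies an instantaneous perturbation (for example a transient severe
#' infection) to a comorbidity state. Combined with [classify_basin()] this
#' implements escape-by-perturbation experiments: a displacement across the
#' separatrix moves the state from the dormant to the fatal basin.
#'
#' @param X,Y Current non-negative burdens.
#' @param dX,dY Displacements; the result must be non-negative.
#' @return A tibble with columns `X`, `Y`.
#' @export
perturb_state <- function(X, Y, dX = 0, dY = 0) {
  nX <- X + dX; nY <- Y + dY
  if (any(nX < 0) || any(nY < 0)) abort("perturbed state must be non-negative")
  tibble(X = nX, Y = nY)
}
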