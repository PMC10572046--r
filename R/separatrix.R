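# Separatrix (stable manifold of the interior saddle) and basins of
# attraction.

#' Compute the separatrix through the interior saddle
#'
#' The threshold curve dividing the dormant from the fatal basin is the
#' stable manifold of the interior saddle. It is traced by integrating the
#' time-reversed flow from two points displaced `delta` along the saddle's
#' stable eigenvector, until the trajectory reaches the boundary of the
#' unit square (backward-time limits on the boundary, such as the unstable
#' healthy origin, are approached asymptotically and truncated there).
#'
#' @param clusters A [ric_clusters] object.
#' @param states Optional precomputed result of [find_steady_states()].
#' @param delta Initial displacement along the stable eigenvector.
#' @param t_max Backward-time horizon.
#' @param step Output time step of the polyline.
#' @return An object of class `ric_separatrix`: a list with `points` (a
#'   tibble of ordered `X`, `Y` polyline vertices) and `saddle` (one-row
#'   tibble). `NULL` if no interior saddle exists (monostable case).
#' @export
compute_separatrix <- function(clusters, states = NULL, delta = 1e-6,
                               t_max = 200, step = 0.02) {
  stopifnot(inherits(clusters, "ric_clusters"))
  cl <- clusters
  if (is.null(states)) states <- find_steady_states(cl)
  sad <- dplyr::filter(states, .data$role == "threshold",
                       .data$stability == "saddle")
  if (nrow(sad) == 0) return(NULL)
  sad <- sad[1, ]
  J <- ric_jacobian(sad$X, sad$Y, cl)
  e <- eigen(J)
  v <- Re(e$vectors[, which.min(Re(e$values))])
  v <- v / sqrt(sum(v^2))
  back <- function(t, s, p) {
    d <- .rhs_num(s[1], s[2], cl)
    list(c(-d$dX, -d$dY))
  }
  rootf <- function(t, s, p) min(s[1], s[2], 1 - s[1], 1 - s[2]) - 1e-9
  trace_branch <- function(z0) {
    out <- deSolve::lsodar(z0, seq(0, t_max, by = step), back, parms = NULL,
                           rtol = 1e-10, atol = 1e-12, rootfunc = rootf)
    cbind(out[, 2], out[, 3])
  }
  b1 <- trace_branch(c(sad$X, sad$Y) + delta * v)
  b2 <- trace_branch(c(sad$X, sad$Y) - delta * v)
  pts <- rbind(b1[rev(seq_len(nrow(b1))), , drop = FALSE],
               c(sad$X, sad$Y),
               b2)
  structure(
    list(points = tibble(X = pts[, 1], Y = pts[, 2]), saddle = sad),
    class = "ric_separatrix"
  )
}

#' @export
print.ric_separatrix <- function(x, ...) {
  cat(sprintf("<ric_separatrix> %d vertices through saddle (%.4g, %.4g)\n",
              nrow(x$points), x$saddle$X, x$saddle$Y))
  invisible(x)
}

#' Which side of the separatrix a point lies on
#'
#' Signed side indicator based on the cross product with the nearest
#' polyline segment; positive values lie on the same side as the fatal
#' state (above the curve), negative on the dormant side.
#'
#' @param sep A `ric_separatrix` object.
#' @param X,Y Point coordinates (vectorized).
#' @param fatal One-row data frame with the fatal state's `X`, `Y`, used to
#'   orient the sign; if `NULL` the raw signed cross product is returned.
#' @return Numeric vector of signed side indicators.
#' @export
separatrix_side <- function(sep, X, Y, fatal = NULL) {
  stopifnot(inherits(sep, "ric_separatrix"))
  p <- sep$points
  # thin the polyline for the nearest-segment search
  idx <- unique(c(seq(1, nrow(p), by = max(1, nrow(p) %/% 2000)), nrow(p)))
  px <- p$X[idx]; py <- p$Y[idx]
  side_one <- function(x0, y0) {
    d2 <- (px - x0)^2 + (py - y0)^2
    i <- which.min(d2)
    i0 <- max(1, i - 1); i1 <- min(length(px), i + 1)
    (px[i1] - px[i0]) * (y0 - py[i0]) - (py[i1] - py[i0]) * (x0 - px[i0])
  }
  s <- vapply(seq_along(X), function(k) side_one(X[k], Y[k]), numeric(1))
  if (!is.null(fatal)) {
    s_f <- side_one(fatal$X[1], fatal$Y[1])
    s <- s * sign(s_f)
  }
  s
}

# Batched forward-flow classification. Integrates many initial states as
# one vectorized ODE system, dropping points as they converge to within
# conv_tol of a stable state (or below the extinction floor).
.flow_classify <- function(pts, cl, stable_states, rtol = 1e-8, atol = 1e-10,
                           t_max = 600, chunk = 25, conv_tol = 1e-5,
                           floor = 1e-9) {
  n <- nrow(pts)
  res <- rep(NA_character_, n)
  act <- seq_len(n)
  X <- pts[, 1]; Y <- pts[, 2]
  rhs_batch <- function(t, s, p) {
    m <- length(s) %/% 2
    d <- .rhs_num(s[seq_len(m)], s[m + seq_len(m)], cl)
    list(c(d$dX, d$dY))
  }
  label_of <- function(x, y) {
    if (x < floor && y < floor) return("eradicated")
    if (nrow(stable_states)) {
      d2 <- (stable_states$X - x)^2 + (stable_states$Y - y)^2
      i <- which.min(d2)
      if (sqrt(d2[i]) < conv_tol) return(stable_states$role[i])
    }
    NA_character_
  }
  t_done <- 0
  while (length(act) && t_done < t_max) {
    s0 <- c(X[act], Y[act])
    out <- deSolve::ode(s0, c(0, chunk), rhs_batch, parms = NULL,
                        method = "ode45", rtol = rtol, atol = atol)
    fin <- out[nrow(out), -1]
    m <- length(act)
    X[act] <- fin[seq_len(m)]
    Y[act] <- fin[m + seq_len(m)]
    lab <- vapply(act, function(i) label_of(X[i], Y[i]), character(1))
    res[act] <- lab
    act <- act[is.na(lab)]
    t_done <- t_done + chunk
  }
  res
}

#' Classify initial states by their attractor
#'
#' Integrates the dimensionless model forward from each `(X, Y)` until the
#' trajectory comes within `conv_tol` of a stable steady state, returning
#' that state's role, or until both burdens fall below the extinction floor
#' (`"eradicated"`). States that fail to converge within `t_max` give `NA`
#' with a warning.
#'
#' @param X,Y Non-negative coordinates (vectorized).
#' @param clusters A [ric_clusters] object.
#' @param states Optional precomputed [find_steady_states()] result.
#' @param rtol,atol Integration tolerances.
#' @param t_max Integration horizon (dimensionless time).
#' @param conv_tol Convergence radius around a stable state.
#' @param floor Extinction floor below which a burden counts as zero.
#' @return Character vector: `"dormant"`, `"fatal"`, `"eradicated"` (or the
#'   role of another stable attractor), `NA` on non-convergence.
#' @export
classify_basin <- function(X, Y, clusters, states = NULL,
                           rtol = 1e-8, atol = 1e-10, t_max = 600,
                           conv_tol = 1e-5, floor = 1e-9) {
  stopifnot(inherits(clusters, "ric_clusters"), length(X) == length(Y))
  if (any(X < 0) || any(Y < 0)) abort("X and Y must be non-negative")
  if (is.null(states)) states <- find_steady_states(clusters)
  stable <- dplyr::filter(states, .data$stability == "stable")
  res <- .flow_classify(cbind(X, Y), clusters, stable,
                        rtol = rtol, atol = atol, t_max = t_max,
                        conv_tol = conv_tol, floor = floor)
  if (anyNA(res)) {
    warn(sprintf("%d state(s) did not converge within t_max = %g",
                 sum(is.na(res)), t_max))
  }
  res
}

#' Basin-of-attraction grid
#'
#' Classifies an `n x n` lattice over the open unit square by forward flow.
#'
#' @param clusters A [ric_clusters] object.
#' @param n Lattice resolution per axis.
#' @inheritParams classify_basin
#' @return A tibble with columns `X`, `Y`, `basin`.
#' @export
basin_grid <- function(clusters, n = 200, rtol = 1e-8, atol = 1e-10,
                       t_max = 600) {
  g <- seq(1 / (2 * n), 1 - 1 / (2 * n), length.out = n)
  X <- rep(g, times = n); Y <- rep(g, each = n)
  tibble(X = X, Y = Y,
         basin = classify_basin(X, Y, clusters, rtol = rtol, atol = atol,
                                t_max = t_max))
}
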