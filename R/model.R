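# Model right-hand sides, Jacobian, simulation and the eradication check.
#
# Dimensionless form (X = x/K_x, Y = y/K_y, T = a_x t):
#   X' = X(1 - X) - A1 X^2 / ((A2 X + A3 Y + 1)(A4 X + 1))
#   Y' = B0 Y(1 - Y) - B1 Y^2 / ((A2 X + A3 Y + 1)(B4 Y + 1))
# The shared denominator A2 X + A3 Y + 1 carries the competition for the
# naive T-cell pool; it is the only coupling between the two diseases.

# fast numeric kernel, vectorized over X, Y
.rhs_num <- function(X, Y, cl) {
  D <- cl$A2 * X + cl$A3 * Y + 1
  list(dX = X * (1 - X) - cl$A1 * X^2 / (D * (cl$A4 * X + 1)),
       dY = cl$B0 * Y * (1 - Y) - cl$B1 * Y^2 / (D * (cl$B4 * Y + 1)))
}

#' Dimensionless model right-hand side
#'
#' Evaluates the normalized growth rates of both disease burdens. Inputs are
#' vectorized.
#'
#' @param X,Y Non-negative normalized disease burdens.
#' @param clusters A [ric_clusters] object.
#' @return A tibble with columns `dX`, `dY`.
#' @export
ric_rhs <- function(X, Y, clusters) {
  stopifnot(inherits(clusters, "ric_clusters"))
  if (any(X < 0) || any(Y < 0)) abort("X and Y must be non-negative")
  d <- .rhs_num(X, Y, clusters)
  tibble(dX = d$dX, dY = d$dY)
}

#' Dimensional model right-hand side
#'
#' Evaluates the growth rates of the two disease populations (in cells per
#' unit time) for the fourteen-parameter dimensional model. Inputs are
#' vectorized.
#'
#' @param x,y Non-negative disease sizes (cells).
#' @param params A [ric_params] object.
#' @return A tibble with columns `dx`, `dy`.
#' @export
ric_rhs_full <- function(x, y, params) {
  stopifnot(inherits(params, "ric_params"))
  if (any(x < 0) || any(y < 0)) abort("x and y must be non-negative")
  p <- params
  shared <- p$beta_x / p$epsilon * x + p$beta_y / p$epsilon * y + 1
  dx <- p$a_x * x * (1 - x / p$K_x) -
    (p$alpha * p$r_x * p$p_x * p$beta_x / (p$d_x * p$epsilon)) * x^2 /
      (shared * (p$r_x * (1 - p$p_x) / p$d_x * x + 1))
  dy <- p$a_y * y * (1 - y / p$K_y) -
    (p$alpha * p$r_y * p$p_y * p$beta_y / (p$d_y * p$epsilon)) * y^2 /
      (shared * (p$r_y * (1 - p$p_y) / p$d_y * y + 1))
  tibble(dx = dx, dy = dy)
}

# analytic Jacobian entries, vectorized; returns list of four vectors
.jac_num <- function(X, Y, cl) {
  D <- cl$A2 * X + cl$A3 * Y + 1
  P <- cl$A4 * X + 1
  Q <- cl$B4 * Y + 1
  list(
    j11 = 1 - 2 * X -
      cl$A1 * X * (2 * D * P - X * (cl$A2 * P + cl$A4 * D)) / (D^2 * P^2),
    j12 = cl$A1 * X^2 * cl$A3 / (D^2 * P),
    j21 = cl$B1 * Y^2 * cl$A2 / (D^2 * Q),
    j22 = cl$B0 * (1 - 2 * Y) -
      cl$B1 * Y * (2 * D * Q - Y * (cl$A3 * Q + cl$B4 * D)) / (D^2 * Q^2)
  )
}

#' Jacobian of the dimensionless model
#'
#' Analytic partial derivatives of the dimensionless right-hand side. The
#' off-diagonal entries are non-negative: raising either disease burden
#' dilutes the shared naive T-cell pool and so weakens the immune pressure
#' on the other disease.
#'
#' @param X,Y Scalar non-negative state.
#' @param clusters A [ric_clusters] object.
#' @return A 2x2 numeric matrix.
#' @export
ric_jacobian <- function(X, Y, clusters) {
  stopifnot(inherits(clusters, "ric_clusters"),
            length(X) == 1, length(Y) == 1)
  if (X < 0 || Y < 0) abort("X and Y must be non-negative")
  j <- .jac_num(X, Y, clusters)
  matrix(c(j$j11, j$j21, j$j12, j$j22), 2, 2)
}

#' Simulate the dimensionless model
#'
#' Integrates the normalized system with an adaptive, implicit-capable
#' solver (`deSolve::lsoda`). Tolerances default to `rtol = 1e-8`,
#' `atol = 1e-10`: trajectories hug the axes where the dynamics are slow, so
#' tight absolute control matters.
#'
#' @param clusters A [ric_clusters] object.
#' @param X0,Y0 Non-negative initial burdens.
#' @param t_end End of the integration (dimensionless time `T = a_x t`).
#' @param n Number of equally spaced output times.
#' @param rtol,atol Integration tolerances.
#' @return A tibble with columns `T`, `X`, `Y`.
#' @export
simulate_ric <- function(clusters, X0, Y0, t_end, n = 400,
                         rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(clusters, "ric_clusters"))
  if (X0 < 0 || Y0 < 0) abort("initial state must be non-negative")
  f <- function(t, s, p) {
    d <- .rhs_num(s[1], s[2], clusters)
    list(c(d$dX, d$dY))
  }
  out <- deSolve::lsoda(c(X = X0, Y = Y0), seq(0, t_end, length.out = n),
                        f, parms = NULL, rtol = rtol, atol = atol)
  tibble(T = out[, 1], X = out[, 2], Y = out[, 3])
}

#' Simulate the dimensional model
#'
#' @param params A [ric_params] object.
#' @param x0,y0 Non-negative initial disease sizes (cells).
#' @param t_end End of the integration (time units of `1/a_x`).
#' @inheritParams simulate_ric
#' @return A tibble with columns `t`, `x`, `y`.
#' @export
simulate_ric_full <- function(params, x0, y0, t_end, n = 400,
                              rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "ric_params"))
  if (x0 < 0 || y0 < 0) abort("initial state must be non-negative")
  f <- function(t, s, p) {
    d <- ric_rhs_full(s[1], s[2], params)
    list(c(d$dx, d$dy))
  }
  out <- deSolve::lsoda(c(x = x0, y = y0), seq(0, t_end, length.out = n),
                        f, parms = NULL, rtol = rtol, atol = atol)
  tibble(t = out[, 1], x = out[, 2], y = out[, 3])
}

#' Safe immune response (eradication) check
#'
#' A disease is eradicated as soon as it is initiated when the model's
#' growth rate at a single cell is already negative. For the cancer this is
#' the printed inequality
#' `a_x (1 - 1/K_x) < alpha r_x p_x beta_x / (d_x epsilon) /
#'  ((beta_x/epsilon + 1)(r_x(1 - p_x)/d_x + 1))`,
#' i.e. negativity of the dimensional right-hand side at `x = 1`, `y = 0`;
#' the mirrored check for the infection swaps the disease indices and uses
#' `a_y` on the left. Note the inequality contains no cross-disease term:
#' it certifies eradication of a disease appearing alone.
#'
#' @param params A [ric_params] object.
#' @param disease `"both"` (default), `"x"` or `"y"`.
#' @return A logical scalar: `TRUE` if the requested disease(s) would be
#'   eradicated at initiation.
#' @export
is_safe_immune <- function(params, disease = c("both", "x", "y")) {
  stopifnot(inherits(params, "ric_params"))
  disease <- match.arg(disease)
  p <- params
  safe_x <- p$a_x * (1 - 1 / p$K_x) <
    p$alpha * p$r_x * p$p_x * p$beta_x / (p$d_x * p$epsilon) /
      ((p$beta_x / p$epsilon + 1) * (p$r_x * (1 - p$p_x) / p$d_x + 1))
  safe_y <- p$a_y * (1 - 1 / p$K_y) <
    p$alpha * p$r_y * p$p_y * p$beta_y / (p$d_y * p$epsilon) /
      ((p$beta_y / p$epsilon + 1) * (p$r_y * (1 - p$p_y) / p$d_y + 1))
  switch(disease, x = safe_x, y = safe_y, both = safe_x && safe_y)
}
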