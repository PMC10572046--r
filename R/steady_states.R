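# Steady-state location and classification.
#
# Interior equilibria (X > 0, Y > 0) satisfy the reduced system
#   f(X, Y) = (1 - X)(A2 X + A3 Y + 1)(A4 X + 1) - A1 X = 0
#   g(X, Y) = B0 (1 - Y)(A2 X + A3 Y + 1)(B4 Y + 1) - B1 Y = 0
# obtained by dividing the right-hand sides by X (resp. Y), which removes
# the axis roots and leaves a well-conditioned Newton problem. Boundary
# equilibria are the origin plus the real roots in (0, 1] of the axis
# cubics, solved directly with polyroot().

.reduced_fg <- function(X, Y, cl) {
  D <- cl$A2 * X + cl$A3 * Y + 1
  list(f = (1 - X) * D * (cl$A4 * X + 1) - cl$A1 * X,
       g = cl$B0 * (1 - Y) * D * (cl$B4 * Y + 1) - cl$B1 * Y)
}

# Newton seeds: a regular lattice plus log-spaced points near the origin,
# where the dormant state sits when the immune response is strong.
.newton_seeds <- function(n_grid) {
  reg <- seq(0.0025, 0.9995, length.out = n_grid)
  lg <- 10^seq(-5, -0.7, length.out = 12)
  xs <- sort(unique(c(reg, lg)))
  list(X = rep(xs, times = length(xs)), Y = rep(xs, each = length(xs)))
}

# All interior roots of the reduced system, deduplicated. Vectorized damped
# Newton iteration over the full seed set at once.
.interior_roots <- function(cl, n_grid = 48, tol = 1e-11) {
  s <- .newton_seeds(n_grid)
  X <- s$X; Y <- s$Y
  A2 <- cl$A2; A3 <- cl$A3; A4 <- cl$A4; B4 <- cl$B4
  B0 <- cl$B0; A1 <- cl$A1; B1 <- cl$B1
  for (it in 1:80) {
    D <- A2 * X + A3 * Y + 1
    f <- (1 - X) * D * (A4 * X + 1) - A1 * X
    g <- B0 * (1 - Y) * D * (B4 * Y + 1) - B1 * Y
    fx <- -D * (A4 * X + 1) + (1 - X) * A2 * (A4 * X + 1) +
      (1 - X) * D * A4 - A1
    fy <- (1 - X) * A3 * (A4 * X + 1)
    gx <- B0 * (1 - Y) * A2 * (B4 * Y + 1)
    gy <- -B0 * D * (B4 * Y + 1) + B0 * (1 - Y) * A3 * (B4 * Y + 1) +
      B0 * (1 - Y) * D * B4 - B1
    det <- fx * gy - fy * gx
    det[abs(det) < 1e-300] <- NA
    dX <- (f * gy - g * fy) / det
    dY <- (fx * g - f * gx) / det
    X <- X - dX
    Y <- Y - dY
    bad <- !is.finite(X) | !is.finite(Y) | abs(X) > 10 | abs(Y) > 10
    X[bad] <- NA
    Y[bad] <- NA
  }
  fg <- .reduced_fg(X, Y, cl)
  scale_f <- pmax(1, abs(A1 * X))
  scale_g <- pmax(1, abs(B1 * Y))
  ok <- is.finite(X) & is.finite(Y) &
    abs(fg$f) < 1e-9 * scale_f & abs(fg$g) < 1e-9 * scale_g &
    X > 1e-7 & Y > 1e-7 & X <= 1 + 1e-9 & Y <= 1 + 1e-9
  if (!any(ok)) return(matrix(numeric(0), 0, 2))
  m <- cbind(X[ok], Y[ok])
  m <- m[!duplicated(round(log10(m), 5)), , drop = FALSE]
  if (nrow(m) > 1) {  # merge anything within 1e-6 (absolute) Euclidean
    dd <- as.matrix(stats::dist(m))
    keep <- rep(TRUE, nrow(m))
    for (i in seq_len(nrow(m) - 1)) {
      if (keep[i]) keep[which(dd[i, ] < 1e-6 & seq_len(nrow(m)) > i)] <- FALSE
    }
    m <- m[keep, , drop = FALSE]
  }
  m
}

# real roots in (0, 1] of the x-axis cubic
# (1 - X)(A2 X + 1)(A4 X + 1) - A1 X = 0
.axis_roots_x <- function(cl) {
  co <- c(1,
          cl$A2 + cl$A4 - 1 - cl$A1,
          cl$A2 * cl$A4 - cl$A2 - cl$A4,
          -cl$A2 * cl$A4)
  .real_unit_roots(co)
}

# real roots in (0, 1] of the y-axis cubic
# B0 (1 - Y)(A3 Y + 1)(B4 Y + 1) - B1 Y = 0
.axis_roots_y <- function(cl) {
  co <- c(cl$B0,
          cl$B0 * (cl$A3 + cl$B4 - 1) - cl$B1,
          cl$B0 * (cl$A3 * cl$B4 - cl$A3 - cl$B4),
          -cl$B0 * cl$A3 * cl$B4)
  .real_unit_roots(co)
}

.real_unit_roots <- function(co) {
  co <- co[seq_len(max(which(co != 0)))]
  if (length(co) < 2) return(numeric(0))
  z <- polyroot(co)
  r <- Re(z[abs(Im(z)) < 1e-8])
  sort(unique(r[r > 1e-12 & r <= 1 + 1e-12]))
}

.classify_jacobian <- function(X, Y, cl) {
  j <- .jac_num(X, Y, cl)
  J <- matrix(c(j$j11, j$j21, j$j12, j$j22), 2, 2)
  ev <- eigen(J, only.values = TRUE)$values
  re <- Re(ev)
  stability <- if (all(re < 0)) "stable" else if (all(re > 0)) "unstable" else "saddle"
  list(stability = stability, ev = ev)
}

#' Find and classify all steady states in the unit square
#'
#' Locates every equilibrium of the dimensionless model in `[0,1]^2`:
#' the healthy origin, the single-disease axis states (roots of the axis
#' cubics) and the interior comorbidity states (Newton iteration on the
#' reduced nullcline system, seeded from a lattice). Stability is read off
#' the eigenvalues of the analytic Jacobian. Interior stable states are
#' labelled `dormant` / `fatal` by total burden `X + Y` (ties broken by
#' `X`); interior non-stable states are labelled `threshold`.
#'
#' @param clusters A [ric_clusters] object.
#' @param n_grid Newton seed lattice resolution per axis.
#' @param tol Residual tolerance on the right-hand side at accepted roots.
#' @return A tibble with one row per steady state and columns `X`, `Y`,
#'   `stability` (`stable`/`saddle`/`unstable`), `role` (`healthy`,
#'   `mono_x`, `mono_y`, `dormant`, `fatal`, `threshold`), `eig1_re`,
#'   `eig1_im`, `eig2_re`, `eig2_im`.
#' @export
find_steady_states <- function(clusters, n_grid = 48, tol = 1e-8) {
  stopifnot(inherits(clusters, "ric_clusters"))
  cl <- clusters
  pts <- rbind(
    cbind(0, 0),
    if (length(ax <- .axis_roots_x(cl))) cbind(ax, 0),
    if (length(ay <- .axis_roots_y(cl))) cbind(0, ay),
    .interior_roots(cl, n_grid = n_grid)
  )
  res <- purrr::map_dfr(seq_len(nrow(pts)), function(i) {
    X <- pts[i, 1]; Y <- pts[i, 2]
    d <- .rhs_num(X, Y, cl)
    if (sqrt(d$dX^2 + d$dY^2) >= tol) {
      warn(sprintf("root at (%.3g, %.3g) exceeds residual tolerance; dropped",
                   X, Y))
      return(NULL)
    }
    k <- .classify_jacobian(X, Y, cl)
    tibble(X = X, Y = Y, stability = k$stability,
           eig1_re = Re(k$ev[1]), eig1_im = Im(k$ev[1]),
           eig2_re = Re(k$ev[2]), eig2_im = Im(k$ev[2]))
  })
  interior <- res$X > 1e-7 & res$Y > 1e-7
  role <- character(nrow(res))
  role[res$X <= 1e-7 & res$Y <= 1e-7] <- "healthy"
  role[res$X > 1e-7 & res$Y <= 1e-7] <- "mono_x"
  role[res$X <= 1e-7 & res$Y > 1e-7] <- "mono_y"
  int_stable <- which(interior & res$stability == "stable")
  if (length(int_stable)) {
    burden <- res$X[int_stable] + res$Y[int_stable]
    ord <- order(burden, res$X[int_stable])
    if (length(int_stable) == 1) {
      # single interior stable state: dormant vs fatal decided by burden
      role[int_stable] <- if (burden < 1) "dormant" else "fatal"
    } else {
      role[int_stable[ord[1]]] <- "dormant"
      role[int_stable[ord[length(ord)]]] <- "fatal"
      if (length(int_stable) > 2) {
        role[int_stable[ord[-c(1, length(ord))]]] <- "dormant"
      }
    }
  }
  role[interior & res$stability != "stable"] <- "threshold"
  res$role <- role
  res[, c("X", "Y", "stability", "role",
          "eig1_re", "eig1_im", "eig2_re", "eig2_im")]
}

#' Nullclines of the dimensionless model
#'
#' The interior part of each nullcline is an explicit function of one
#' variable because the reduced equations are linear in the opposite
#' variable; the axes `X = 0` and `Y = 0` are always nullclines too.
#'
#' @param clusters A [ric_clusters] object.
#' @param n Number of sample points per curve.
#' @return A tibble with columns `curve` (`"dX=0"` or `"dY=0"`), `X`, `Y`,
#'   restricted to the unit square.
#' @export
nullclines <- function(clusters, n = 600) {
  stopifnot(inherits(clusters, "ric_clusters"))
  cl <- clusters
  Xs <- seq(1e-6, 1 - 1e-9, length.out = n)
  Yx <- if (cl$A3 > 0) {
    (cl$A1 * Xs / ((1 - Xs) * (cl$A4 * Xs + 1)) - cl$A2 * Xs - 1) / cl$A3
  } else rep(NA_real_, n)
  Ys <- seq(1e-6, 1 - 1e-9, length.out = n)
  Xy <- if (cl$A2 > 0) {
    (cl$B1 * Ys / (cl$B0 * (1 - Ys) * (cl$B4 * Ys + 1)) - cl$A3 * Ys - 1) / cl$A2
  } else rep(NA_real_, n)
  out <- dplyr::bind_rows(
    tibble(curve = "dX=0", X = Xs, Y = Yx),
    tibble(curve = "dY=0", X = Xy, Y = Ys)
  )
  dplyr::filter(out, is.finite(.data$X), is.finite(.data$Y),
                .data$X >= 0, .data$X <= 1, .data$Y >= 0, .data$Y <= 1)
}
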