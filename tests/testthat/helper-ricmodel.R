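# Shared fixtures: random parameter sets are generated in code, never stored.

# random dimensional parameter set with broad log-uniform physiology
random_full_params <- function() {
  lu <- function(lo, hi) exp(runif(1, log(lo), log(hi)))
  ric_params(
    a_x = lu(0.1, 5), a_y = lu(0.1, 5),
    K_x = lu(10, 1e5), K_y = lu(10, 1e5),
    alpha = lu(0.1, 200), epsilon = lu(0.1, 5),
    beta_x = lu(1e-4, 1), beta_y = lu(1e-4, 1),
    p_x = runif(1, 0.05, 0.995), p_y = runif(1, 0.05, 0.995),
    d_x = lu(0.1, 5), d_y = lu(0.1, 5),
    r_x = lu(1e-4, 1), r_y = lu(1e-4, 1)
  )
}

# random dimensionless cluster set
random_clusters <- function() {
  lu <- function(lo, hi) exp(runif(1, log(lo), log(hi)))
  ric_clusters(
    A1 = lu(0.1, 1e3), A2 = lu(0.1, 100), A3 = lu(0.1, 100),
    A4 = lu(0.1, 100), B0 = lu(0.2, 5), B1 = lu(0.1, 1e3),
    B4 = lu(0.1, 100)
  )
}

# nullcline-restriction oracle for interior equilibria: each nullcline is
# an explicit curve of one variable (the reduced equations are linear in
# the opposite variable); interior steady states are the sign changes of
# the other equation restricted to that curve, refined by uniroot. Both
# restrictions are scanned and their roots merged, so a root sitting in a
# thin validity band of one curve is still caught on the other. Fully
# independent of the package's 2-D Newton solver.
oracle_interior_states <- function(cl, n = 2000) {
  lg <- exp(seq(log(1e-7), log(0.5), length.out = n))
  grid <- sort(unique(c(lg, 1 - lg)))
  scan_curve <- function(curve_of, other_eq) {
    roots <- NULL
    v <- curve_of(grid)
    valid <- is.finite(v) & v > 0 & v < 1
    G <- ifelse(valid, other_eq(grid), NA)
    idx <- which(!is.na(G[-1]) & !is.na(G[-length(G)]) &
                   sign(G[-1]) * sign(G[-length(G)]) < 0)
    for (i in idx) {
      r <- uniroot(other_eq, c(grid[i], grid[i + 1]), tol = 1e-12)$root
      roots <- rbind(roots, c(r, curve_of(r)))
    }
    roots
  }
  Yf <- function(X) {
    (cl$A1 * X / ((1 - X) * (cl$A4 * X + 1)) - cl$A2 * X - 1) / cl$A3
  }
  g_on_x <- function(X) {
    Y <- Yf(X)
    cl$B0 * (1 - Y) * (cl$A2 * X + cl$A3 * Y + 1) * (cl$B4 * Y + 1) -
      cl$B1 * Y
  }
  Xg <- function(Y) {
    (cl$B1 * Y / (cl$B0 * (1 - Y) * (cl$B4 * Y + 1)) - cl$A3 * Y - 1) /
      cl$A2
  }
  f_on_y <- function(Y) {
    X <- Xg(Y)
    (1 - X) * (cl$A2 * X + cl$A3 * Y + 1) * (cl$A4 * X + 1) - cl$A1 * X
  }
  r1 <- scan_curve(Yf, g_on_x)                  # (X, Y) pairs
  r2 <- scan_curve(Xg, f_on_y)                  # (Y, X) pairs
  if (!is.null(r2)) r2 <- r2[, 2:1, drop = FALSE]
  m <- rbind(r1, r2)
  if (is.null(m) || nrow(m) == 0) return(NULL)
  colnames(m) <- c("X", "Y")
  # merge duplicates found on both curves
  keep <- rep(TRUE, nrow(m))
  if (nrow(m) > 1) {
    dd <- as.matrix(dist(m))
    for (i in seq_len(nrow(m) - 1)) {
      if (keep[i]) keep[which(dd[i, ] < 1e-6 & seq_len(nrow(m)) > i)] <- FALSE
    }
  }
  m[keep, , drop = FALSE]
}
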