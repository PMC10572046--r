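test_that("right-hand sides honour the fixed points and limiting cases", {
  p <- default_params()
  cl <- cluster_params(p)

  # the healthy state is a steady state in both formulations
  expect_equal(unlist(ric_rhs_full(0, 0, p)), c(dx = 0, dy = 0))
  expect_equal(unlist(ric_rhs(0, 0, cl)), c(dX = 0, dY = 0))

  # without naive T-cell production the cancer grows purely logistically
  p0 <- with_alpha(p, 0)
  expect_equal(ric_rhs_full(p0$K_x / 2, 123, p0)$dx, p0$a_x * p0$K_x / 4)

  # uncoupled logistic clusters at the square's centre
  cl0 <- ric_clusters(A1 = 0, A2 = 1, A3 = 1, A4 = 1, B0 = 2, B1 = 0, B4 = 1)
  expect_equal(unlist(ric_rhs(0.5, 0.5, cl0)), c(dX = 0.25, dY = 0.5))

  # on the far corner the logistic terms vanish and the immune terms bite
  d <- ric_rhs(1, 1, cl)
  expect_lt(d$dX, 0)
  expect_lt(d$dY, 0)

  expect_error(ric_rhs(-0.1, 0, cl), "non-negative")
  expect_error(ric_rhs_full(-1, 0, p), "non-negative")
})

test_that("analytic Jacobian matches finite differences and the uncoupled limit", {
  cl0 <- ric_clusters(A1 = 0, A2 = 1, A3 = 1, A4 = 1, B0 = 1.7, B1 = 0,
                      B4 = 1)
  expect_equal(ric_jacobian(0, 0, cl0), diag(c(1, 1.7)))

  set.seed(12)
  h <- 1e-6
  for (k in 1:4) {
    cl <- random_clusters()
    for (j in 1:25) {
      X <- runif(1, 0.01, 0.99); Y <- runif(1, 0.01, 0.99)
      J <- ric_jacobian(X, Y, cl)
      fd <- function(i, dx, dy) {
        a <- ric_rhs(X + dx * h, Y + dy * h, cl)
        b <- ric_rhs(X - dx * h, Y - dy * h, cl)
        (unlist(a) - unlist(b))[i] / (2 * h)
      }
      Jfd <- matrix(c(fd(1, 1, 0), fd(2, 1, 0), fd(1, 0, 1), fd(2, 0, 1)),
                    2, 2)
      expect_equal(J, Jfd, tolerance = 1e-4)
    }
  }
})

test_that("safe immune response: limiting cases and the eradication oracle", {
  p <- default_params()
  # no production: the immune side is zero, growth wins
  expect_false(is_safe_immune(with_alpha(p, 0), "x"))
  # vanishing growth rate is always dominated by a positive immune side
  tiny_growth <- do.call(ric_params,
                         modifyList(unclass(p), list(a_x = 1e-12)))
  expect_true(is_safe_immune(tiny_growth, "x"))

  # a safe constellation eradicates a just-initiated single disease:
  # simulated from one cell the burden decays monotonically below one cell
  psafe <- with_alpha(p, 5000)
  expect_true(is_safe_immune(psafe, "both"))
  tr <- simulate_ric_full(psafe, x0 = 1, y0 = 0, t_end = 20, n = 200)
  expect_true(all(diff(tr$x) < 0))
  expect_lt(tr$x[nrow(tr)], 0.3)
})

test_that("trajectories stay non-negative and are trapped in the unit square", {
  set.seed(33)
  for (k in 1:100) {
    cl <- random_clusters()
    # start outside the square
    tr <- simulate_ric(cl, X0 = runif(1, 1, 3), Y0 = runif(1, 1, 3),
                       t_end = 60, n = 600)
    expect_true(all(tr$X > -1e-12 & tr$Y > -1e-12))
    inside <- which(tr$X <= 1 + 1e-9 & tr$Y <= 1 + 1e-9)
    expect_gt(length(inside), 0)  # enters in finite time
    after <- seq(min(inside), nrow(tr))
    expect_true(all(tr$X[after] <= 1 + 1e-6 & tr$Y[after] <= 1 + 1e-6))
  }
})

test_that("with no cancer immunity the burden follows the logistic closed form", {
  cl <- ric_clusters(A1 = 0, A2 = 3, A3 = 2, A4 = 1, B0 = 1.2, B1 = 40,
                     B4 = 5)
  X0 <- 0.07
  tr <- simulate_ric(cl, X0 = X0, Y0 = 0.4, t_end = 12, n = 300)
  closed <- X0 / (X0 + (1 - X0) * exp(-tr$T))
  expect_lt(max(abs(tr$X - closed)), 1e-6)
})

test_that("simulating the full model and normalizing equals the cluster model", {
  set.seed(91)
  for (k in 1:5) {
    p <- random_full_params()
    cl <- cluster_params(p)
    X0 <- runif(1, 0.05, 0.9); Y0 <- runif(1, 0.05, 0.9)
    t_end <- 8 / p$a_x
    full <- simulate_ric_full(p, X0 * p$K_x, Y0 * p$K_y, t_end, n = 200,
                              rtol = 1e-10, atol = 1e-12)
    # dimensionless time T = a_x t on the same output instants
    dimless <- simulate_ric(cl, X0, Y0, p$a_x * t_end, n = 200,
                            rtol = 1e-10, atol = 1e-12)
    expect_lt(max(abs(full$x / p$K_x - dimless$X)), 1e-6)
    expect_lt(max(abs(full$y / p$K_y - dimless$Y)), 1e-6)
  }
})
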