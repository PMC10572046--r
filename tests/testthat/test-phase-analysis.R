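test_that("the uncoupled logistic system has exactly the four corner states", {
  cl <- ric_clusters(A1 = 0, A2 = 0, A3 = 0, A4 = 0, B0 = 2, B1 = 0, B4 = 0)
  st <- find_steady_states(cl)
  expect_equal(nrow(st), 4)
  expect_setequal(paste(st$X, st$Y), c("0 0", "1 0", "0 1", "1 1"))
  get <- function(x, y) st$stability[st$X == x & st$Y == y]
  expect_equal(get(0, 0), "unstable")
  expect_equal(get(1, 0), "saddle")
  expect_equal(get(0, 1), "saddle")
  expect_equal(get(1, 1), "stable")
})

test_that("the default parameters give two stable interior states and a saddle", {
  st <- find_steady_states(cluster_params(default_params()))
  int <- st[st$role %in% c("dormant", "fatal", "threshold"), ]
  expect_equal(nrow(int), 3)
  expect_equal(sort(int$stability), c("saddle", "stable", "stable"))
  dorm <- int[int$role == "dormant", ]
  fatal <- int[int$role == "fatal", ]
  thr <- int[int$role == "threshold", ]
  expect_equal(thr$stability, "saddle")
  expect_lt(dorm$X + dorm$Y, fatal$X + fatal$Y)
  # every returned state is an equilibrium to tight residual tolerance,
  # and its label matches eigenvalue signs recomputed here
  cl <- cluster_params(default_params())
  for (i in seq_len(nrow(st))) {
    d <- ric_rhs(st$X[i], st$Y[i], cl)
    expect_lt(sqrt(d$dX^2 + d$dY^2), 1e-8)
    ev <- Re(eigen(ric_jacobian(st$X[i], st$Y[i], cl),
                   only.values = TRUE)$values)
    lab <- if (all(ev < 0)) "stable" else if (all(ev > 0)) "unstable"
           else "saddle"
    expect_equal(st$stability[i], lab)
  }
})

test_that("interior states agree with the nullcline-restriction oracle", {
  set.seed(55)
  cases <- c(list(cluster_params(default_params()),
                  cluster_params(default_params(alpha = 20)),
                  cluster_params(default_params(alpha = 110))),
             lapply(1:5, function(i) random_clusters()))
  for (cl in cases) {
    st <- find_steady_states(cl)
    int <- st[st$role %in% c("dormant", "fatal", "threshold"), ]
    orc <- oracle_interior_states(cl)
    n_orc <- if (is.null(orc)) 0 else nrow(orc)
    expect_equal(nrow(int), n_orc)
    if (n_orc > 0) {
      for (i in seq_len(n_orc)) {
        d <- sqrt((int$X - orc[i, 1])^2 + (int$Y - orc[i, 2])^2)
        expect_lt(min(d), 1e-6)
      }
    }
  }
})

test_that("the separatrix passes through the saddle and spans the square", {
  cl <- cluster_params(default_params())
  st <- find_steady_states(cl)
  sep <- compute_separatrix(cl, states = st)
  expect_s3_class(sep, "ric_separatrix")
  sad <- st[st$role == "threshold", ]
  d <- sqrt((sep$points$X - sad$X)^2 + (sep$points$Y - sad$Y)^2)
  expect_lt(min(d), 1e-4)
  ends <- sep$points[c(1, nrow(sep$points)), ]
  edge_dist <- pmin(ends$X, ends$Y, 1 - ends$X, 1 - ends$Y)
  expect_true(all(edge_dist < 1e-6))
  # monostable case: no saddle, no separatrix
  expect_null(compute_separatrix(cluster_params(default_params(alpha = 110))))
})

test_that("forward flow and separatrix side agree for random interior states", {
  cl <- cluster_params(default_params())
  st <- find_steady_states(cl)
  sep <- compute_separatrix(cl, states = st)
  fatal <- st[st$role == "fatal", ]
  set.seed(2024)
  X <- runif(500); Y <- runif(500)
  flow <- classify_basin(X, Y, cl, states = st)
  side <- separatrix_side(sep, X, Y, fatal = fatal)
  geom <- ifelse(side > 0, "fatal", "dormant")
  expect_gte(mean(flow == geom, na.rm = TRUE), 0.99)
})

test_that("basin classification resolves points near the attractors and saddle", {
  cl <- cluster_params(default_params())
  st <- find_steady_states(cl)
  dorm <- st[st$role == "dormant", ]
  sad <- st[st$role == "threshold", ]
  expect_equal(classify_basin(dorm$X + 1e-6, dorm$Y + 1e-6, cl, states = st),
               "dormant")
  # slightly above/below the separatrix near the saddle, displaced along
  # the unstable direction
  J <- ric_jacobian(sad$X, sad$Y, cl)
  e <- eigen(J)
  vu <- Re(e$vectors[, which.max(Re(e$values))])
  vu <- vu * sign(vu[1]) / sqrt(sum(vu^2))  # points toward larger burden
  up <- c(sad$X, sad$Y) + 1e-3 * vu
  dn <- c(sad$X, sad$Y) - 1e-3 * vu
  expect_equal(classify_basin(up[1], up[2], cl, states = st), "fatal")
  expect_equal(classify_basin(dn[1], dn[2], cl, states = st), "dormant")
})

test_that("basin areas are reproducible across integrator tolerances", {
  cl <- cluster_params(default_params())
  g1 <- basin_grid(cl, n = 40, rtol = 1e-8, atol = 1e-10)
  g2 <- basin_grid(cl, n = 40, rtol = 1e-10, atol = 1e-12)
  a1 <- mean(g1$basin == "dormant")
  a2 <- mean(g2$basin == "dormant")
  expect_lt(abs(a1 - a2), 0.01)
})

test_that("subtype classification follows the bifurcation structure", {
  p <- default_params()
  expect_equal(as.character(classify_subtype(p)), "R")
  expect_equal(as.character(classify_subtype(with_alpha(p, 110))), "D")
  expect_equal(as.character(classify_subtype(with_alpha(p, 10))), "F")
  expect_equal(as.character(classify_subtype(with_alpha(p, 5000))), "H")
})

test_that("the healthy state is unstable whenever the response is not safe", {
  set.seed(77)
  n_checked <- 0
  while (n_checked < 20) {
    p <- random_full_params()
    if (is_safe_immune(p, "both")) next
    ev <- Re(eigen(ric_jacobian(0, 0, cluster_params(p)),
                   only.values = TRUE)$values)
    expect_true(all(ev > 0))
    n_checked <- n_checked + 1
  }
})
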