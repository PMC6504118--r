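test_that("normalized Legendre polynomials match closed forms", {
  s <- seq(-1, 1, by = 0.25)
  expect_equal(legendre_poly(0, s), rep(1, length(s)))
  expect_equal(legendre_poly(1, s), sqrt(3) * s)
  expect_equal(legendre_poly(2, 0.5, normalized = FALSE), -0.125)
  for (d in 0:6) expect_equal(legendre_poly(d, 1, normalized = FALSE), 1)
  expect_error(legendre_poly(-1, 0))
})

test_that("the product basis is orthonormal under the uniform input measure", {
  set.seed(11)
  u <- runif(3e4)
  bases <- list(list("0" = 1), list("3" = 1), list("0" = 2),
                list("1" = 1, "4" = 1), list("2" = 3),
                list("0" = 1, "2" = 1, "5" = 2))
  zs <- lapply(bases, function(b) build_target(u, b)$z)
  n <- min(lengths(zs))
  tol <- 4 / sqrt(n)
  for (i in seq_along(zs)) {
    zi <- tail(zs[[i]], n)
    expect_lt(abs(mean(zi * zi) - 1), tol)       # unit norm
    if (i > 1) {
      zj <- tail(zs[[i - 1]], n)
      expect_lt(abs(mean(zi * zj)), tol)         # pairwise orthogonal
    }
  }
})

test_that("a perfect delay line has unit capacity at represented lags", {
  set.seed(2)
  u <- runif(4000)
  K <- 10
  X <- t(vapply(0:K, function(k) c(rep(0.5, k), u[seq_len(length(u) - k)]),
                numeric(length(u))))
  mem <- memory_capacity(X, u, k_max = 25)
  expect_equal(mem$curve[1:(K + 1)], rep(1, K + 1), tolerance = 1e-9)
  expect_equal(mem$curve[(K + 2):26], rep(0, 25 - K))
  expect_equal(mem$C_M, K + 1, tolerance = 1e-9)
  expect_true(all(mem$curve <= 1))
})

test_that("capacity of pure noise matches the finite-sample bias", {
  set.seed(3)
  n_state <- 50; T <- 5000
  cs <- replicate(10, {
    X <- matrix(rnorm(n_state * T), n_state)
    capacity_score(X, rnorm(T))
  })
  expect_lt(abs(mean(cs) - n_state / T) / (n_state / T), 0.2)
})

test_that("capacity equals a brute-force regression oracle on a linear reservoir", {
  set.seed(4)
  T <- 3000
  u <- runif(T)
  A <- matrix(c(0.8, 0.1, 0, 0, 0,
                0.1, 0.6, 0.2, 0, 0,
                0, 0.2, 0.5, 0.1, 0,
                0, 0, 0.1, 0.7, 0.1,
                0, 0, 0, 0.1, 0.4), 5, 5, byrow = TRUE)
  b <- c(1, 0.5, -0.3, 0.2, 0.8)
  X <- matrix(0, 5, T)
  x <- numeric(5)
  for (n in seq_len(T)) {
    x <- A %*% x + b * u[n]
    X[, n] <- x
  }
  z <- build_target(u, list("3" = 1))
  Xa <- X[, (z$offset + 1):T]
  c_pkg <- capacity_score(Xa, z$z)
  # independent oracle: explicit normal-equations regression
  Xc <- t(Xa) - colMeans(t(Xa))[col(t(Xa))]
  zc <- z$z - mean(z$z)
  w <- solve(crossprod(Xc), crossprod(Xc, zc))
  c_brute <- 1 - sum((zc - Xc %*% w)^2) / sum(zc^2)
  expect_equal(c_pkg, c_brute, tolerance = 1e-8)

  # a linear system has no capacity for nonlinear targets
  tc <- total_capacity(X, u, d_max = 3, k_max = 10, k_max_nl = 5)
  expect_gt(tc$by_degree[["d1"]], 0.5)
  # nonlinear capacities of a linear system: only finite-sample residue
  expect_lt(tc$by_degree[["d2"]], 0.05)
  expect_lt(tc$by_degree[["d3"]], 0.05)
  expect_equal(sum(tc$by_degree), tc$C_T)
  expect_lte(tc$C_T, nrow(X))
})

test_that("state harvesting returns the documented shapes and responds to input", {
  mc <- build_microcircuit(120, "Hom", seed = 5)
  hv <- harvest_states(mc, T_steps = 100, delta_t = 10, rho_u = 200,
                       nu_in = 5, seed = 6, washout = 20)
  expect_equal(dim(hv$X), c(mc$sizes[["E"]], 100))
  expect_length(hv$u, 100)
  expect_false(any(is.na(hv$X)))
  hv2 <- harvest_states(mc, T_steps = 100, delta_t = 10, rho_u = 200,
                        nu_in = 5, seed = 7, washout = 20)
  expect_false(identical(hv$X, hv2$X))
})

test_that("optimal-resolution scan returns a coherent capacity curve", {
  mc <- build_microcircuit(120, "Hom", seed = 8)
  sc <- optimal_resolution(mc, dt_grid = c(5, 20), T_steps = 300,
                           rho_u = 300, nu_in = 5, seeds = 9)
  expect_equal(dim(sc$curve), c(2, 1))
  expect_true(all(sc$curve >= 0 & sc$curve <= 1))
  expect_true(is.na(sc$delta_t_star) ||
                sc$mean_curve[match(sc$delta_t_star, c(5, 20))] >= 0.99)
})
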