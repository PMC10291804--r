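test_that("MAP estimates match brute-force grid search", {
  b1 <- bank_1pl()
  # empty pattern: prior mode
  expect_equal(map_estimate(b1, NA_integer_), 0)

  th1 <- map_estimate(b1, 1L)
  grid <- oracle_map_grid_1d(function(t) log(plogis(t)))
  expect_lt(abs(th1[1] - grid), 1e-3)
  expect_equal(th1[1], 0.4013, tolerance = 1e-3)
  # symmetry: response 0 mirrors response 1
  expect_equal(map_estimate(b1, 0L)[1], -th1[1], tolerance = 1e-9)

  # a 1-D-reducible polytomous pattern (general-only item of bank_small)
  b <- bank_small()
  pat <- c(NA, NA, NA, NA, 1L)
  th <- map_estimate(b, pat)
  expect_equal(th[2:3], c(0, 0))       # unprobed dimensions stay at 0
  grid <- oracle_map_grid_1d(function(t)
    log(oracle_grm_prob(c(1, 0, 0), c(0.8, -0.9), c(t, 0, 0))[2]))
  expect_lt(abs(th[1] - grid), 1e-3)
})

test_that("gradient at the MAP is numerically zero", {
  b <- bank_small()
  set.seed(31)
  th0 <- rnorm(3)
  X <- simulate_responses(matrix(th0, 1), b, seed = 5)
  th <- map_estimate(b, X[1, ])
  h <- 1e-5
  for (d in 1:3) {
    e <- numeric(3); e[d] <- h
    g <- (grm_loglik(b, X[1, ], th + e) - (th + e)[d]^2 / 2 -
            grm_loglik(b, X[1, ], th - e) + (th - e)[d]^2 / 2) / (2 * h)
    expect_lt(abs(g), 1e-5)
  }
})

test_that("posterior information is prior + additive item information", {
  b <- bank_small()
  expect_equal(posterior_information(b, rep(NA_integer_, 5), numeric(3)),
               diag(3))
  theta <- c(0.2, -0.4, 0.7)
  patA <- c(1L, NA, 2L, NA, NA)
  patAB <- c(1L, 3L, 2L, NA, 1L)
  IA <- posterior_information(b, patA, theta)
  IAB <- posterior_information(b, patAB, theta)
  expect_equal(IAB - IA,
               grm_item_info(b, 2, theta) + grm_item_info(b, 5, theta),
               tolerance = 1e-12)

  b1 <- bank_1pl()
  th1 <- map_estimate(b1, 1L)
  I1 <- posterior_information(b1, 1L, th1)
  P <- plogis(th1[1])
  expect_equal(I1[1, 1], 1 + P * (1 - P), tolerance = 1e-9)
})

test_that("observed information differs from expected but stays symmetric", {
  b <- bank_small()
  theta <- c(0.2, -0.4, 0.7)
  pat <- c(1L, 3L, 2L, 0L, 1L)
  Io <- posterior_information(b, pat, theta, type = "observed")
  expect_equal(Io, t(Io))
  # numerical Hessian of the log-likelihood agrees with the observed version
  h <- 1e-4
  num <- matrix(0, 3, 3)
  for (r in 1:3) for (s in 1:3) {
    er <- es <- numeric(3); er[r] <- h; es[s] <- h
    num[r, s] <- -(grm_loglik(b, pat, theta + er + es) -
                     grm_loglik(b, pat, theta + er - es) -
                     grm_loglik(b, pat, theta - er + es) +
                     grm_loglik(b, pat, theta - er - es)) / (4 * h^2)
  }
  expect_equal(Io, diag(3) + num, tolerance = 1e-4)
})

test_that("standard errors invert the information and shrink with items", {
  expect_equal(standard_errors(diag(3)), rep(1, 3))
  expect_equal(standard_errors(diag(c(2, 1, 4))),
               c(1 / sqrt(2), 1, 0.5))
  expect_error(standard_errors(matrix(c(1, 2, 2, 1), 2)), "positive definite")

  b <- bank_small()
  theta <- c(0.3, 0.1, -0.2)
  pats <- list(c(1L, NA, NA, NA, NA), c(1L, 3L, NA, NA, NA),
               c(1L, 3L, 2L, NA, NA), c(1L, 3L, 2L, 4L, 1L))
  ses <- t(vapply(pats, function(p)
    standard_errors(posterior_information(b, p, theta)), numeric(3)))
  expect_true(all(diff(ses) < 1e-12))   # non-increasing on every dimension
})

test_that("MAP shrinks relative to unpenalized ML", {
  b <- bank_small()
  set.seed(8)
  X <- simulate_responses(generate_thetas(12, 3, seed = 9), b, seed = 10)
  arr <- bfcat:::bank_arrays(b)
  for (j in 1:12) {
    th_map <- map_estimate(b, X[j, ])
    ml <- optim(th_map, function(t) -grm_loglik(b, X[j, ], t),
                method = "L-BFGS-B", lower = rep(-6, 3), upper = rep(6, 3))
    if (all(abs(ml$par) < 5.9))         # interior ML exists
      expect_lte(sqrt(sum(th_map^2)), sqrt(sum(ml$par^2)) + 1e-6)
  }
})
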