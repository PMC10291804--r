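test_that("category probabilities match direct logistic arithmetic", {
  b <- bank_1pl()
  expect_equal(grm_prob(b, 1, 0), c(0.5, 0.5))

  b4 <- bank_k4()
  theta <- c(0.5, 1, 0)
  p <- grm_prob(b4, "k4", theta)
  # z = 2*0.5 + 1*1 = 2; boundaries at sigma(4), sigma(2), sigma(0)
  expect_equal(p, oracle_grm_prob(c(2, 1, 0), c(2, 0, -2), theta),
               tolerance = 1e-12)
  expect_equal(sum(p), 1)
})

test_that("probabilities are a simplex for random items and thetas", {
  set.seed(71)
  b <- generate_item_bank(bank_spec(), seed = 7)
  for (rep in 1:25) {
    i <- sample(n_items(b), 1)
    th <- rnorm(b$D)
    p <- grm_prob(b, i, th)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    # boundary probabilities strictly decrease when intercepts do
    Ps <- rev(cumsum(rev(p)))[-1]
    if (b$items$n_categories[i] > 2) expect_true(all(diff(Ps) < 0))
  }
})

test_that("dimension mismatch and bad categories are rejected", {
  b <- bank_small()
  expect_error(grm_prob(b, 1, c(0, 0)), "length D")
  expect_error(grm_loglik(b, c(0L, 0L, 0L, 0L, 5L), numeric(3)), "0..K-1")
})

test_that("item information equals w * a a' and the finite-difference Hessian", {
  b <- bank_1pl()
  expect_equal(grm_item_info(b, 1, 0)[1, 1], 0.25)

  b4 <- bank_k4()
  theta <- c(0.5, 1, 0)
  I <- grm_item_info(b4, 1, theta)
  expect_equal(I, t(I))
  expect_equal(qr(I)$rank, 1L)
  # support only on dimensions {general, group 1}
  expect_true(all(I[3, ] == 0) && all(I[, 3] == 0))
  I_fd <- oracle_item_info_fd(c(2, 1, 0), c(2, 0, -2), theta)
  expect_equal(I, I_fd, tolerance = 1e-4)

  # general-only item: single nonzero entry
  b5 <- bank_small()
  I5 <- grm_item_info(b5, 5, c(0.3, -1, 2))
  expect_true(all(I5[-1, ] == 0) && all(I5[, -1] == 0))
  expect_gt(I5[1, 1], 0)
})

test_that("pattern log-likelihood sums per-item log probabilities", {
  b <- bank_small()
  expect_identical(grm_loglik(b, rep(NA_integer_, 5), numeric(3)), 0)
  b1 <- bank_1pl()
  expect_equal(grm_loglik(b1, 1L, 0), log(0.5))

  theta <- c(0.4, -0.8, 1.2)
  pat <- c(1L, 3L, NA, 0L, NA)
  manual <- log(grm_prob(b, 1, theta)[2]) + log(grm_prob(b, 2, theta)[4]) +
    log(grm_prob(b, 4, theta)[1])
  expect_equal(grm_loglik(b, pat, theta), manual, tolerance = 1e-12)
})

test_that("expected score is bounded, monotone in the general trait", {
  b <- bank_1pl()
  expect_equal(grm_expected_score(b, 1, 0), 0.5)
  b4 <- bank_k4()
  theta <- c(0.5, 1, 0)
  p <- oracle_grm_prob(c(2, 1, 0), c(2, 0, -2), theta)
  expect_equal(grm_expected_score(b4, 1, theta), sum(0:3 * p),
               tolerance = 1e-12)
  es <- vapply(seq(-3, 3, by = 0.5),
               function(t0) grm_expected_score(b4, 1, c(t0, 0, 0)),
               numeric(1))
  expect_true(all(diff(es) > 0))
  expect_true(all(es >= 0 & es <= 3))
})

test_that("difficulty <-> intercept conversion round-trips", {
  expect_equal(intercepts_from_difficulties(1, 0, c(-1, 0, 1)), c(1, 0, -1))
  expect_equal(intercepts_from_difficulties(2, 1, 0.5), -0.5 * sqrt(5))
  b <- c(-1.3, 0.2, 0.9)
  d <- intercepts_from_difficulties(1.7, 0.6, b)
  expect_true(all(diff(d) < 0))
  expect_equal(difficulties_from_intercepts(1.7, 0.6, d), b)
  expect_error(intercepts_from_difficulties(1, 0, c(1, 0)), "increasing")
})

test_that("item bank validation enforces the invariants", {
  df <- bank_small()$items
  bad <- df; bad$d1[2] <- -3            # increasing intercepts
  expect_error(item_bank(bad, G = 2), "decreasing")
  bad <- df; bad$a_general[1] <- -1
  expect_error(item_bank(bad, G = 2), "positive")
  bad <- df; bad$item_id[2] <- "s1"
  expect_error(item_bank(bad, G = 2), "duplicated")
  bad <- df; bad$a_group[5] <- 0.5      # general-only with group slope
  expect_error(item_bank(bad, G = 2), "general-only")
})
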