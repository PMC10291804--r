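# Calibration unit tests run at reduced problem sizes; the full-scale
# recovery checks live in the acceptance suite.

test_that("EM ascends and recovers a two-group bank", {
  b <- bank_recovery()
  th <- generate_thetas(800, 3, seed = 62)
  X <- simulate_responses(th, b, seed = 63)
  fit <- bfgrm(X, structure = setNames(b$items$group_index,
                                       b$items$item_id),
               max_cycles = 200, tol_loglik = 1e-5)
  expect_s3_class(fit, "bfgrm")
  expect_true(all(diff(fit$loglik) > -1e-8))
  expect_true(fit$converged)
  est <- fit$bank$items
  expect_gt(cor(est$a_general, b$items$a_general), 0.9)
  expect_gt(cor(est$a_group, b$items$a_group), 0.85)
  expect_silent(validate_item_bank(fit$bank))
  # missing data: FIML drops the entries without breaking the fit
  set.seed(64)
  Xm <- X; Xm[sample(length(Xm), length(Xm) %/% 10)] <- NA
  fitm <- bfgrm(Xm, structure = setNames(b$items$group_index,
                                         b$items$item_id), max_cycles = 40)
  expect_true(all(diff(fitm$loglik) > -1e-8))
  expect_gt(cor(fitm$bank$items$a_general, b$items$a_general), 0.85)
})

test_that("unobserved categories collapse with a warning, or error in strict mode", {
  b <- bank_small()
  th <- generate_thetas(150, 3, seed = 71)
  X <- simulate_responses(th, b, seed = 72)
  X[, 2][X[, 2] == 3L] <- 2L            # wipe out the top category
  expect_warning(
    fit <- bfgrm(X, structure = setNames(b$items$group_index,
                                         b$items$item_id),
                 n_categories = b$items$n_categories, max_cycles = 5),
    "collapsing")
  expect_equal(fit$bank$items$n_categories[2], 3L)
  expect_error(
    suppressWarnings(
      bfgrm(X, structure = setNames(b$items$group_index, b$items$item_id),
            n_categories = b$items$n_categories, unobserved = "error",
            max_cycles = 5)),
    "unobserved")
})

test_that("Q3 under local independence stays below the flagging threshold", {
  b <- bank_recovery()
  th <- generate_thetas(600, 3, seed = 81)
  X <- simulate_responses(th, b, seed = 82)
  q3 <- q3_matrix(X, b)
  expect_equal(unclass(q3), t(unclass(q3)))
  v <- q3[upper.tri(q3)]
  expect_true(all(v >= -1 & v <= 1))
  expect_lt(max(v), 0.2)                # nothing flagged under independence
  gi <- b$items$group_index
  cross <- upper.tri(q3) & !outer(gi, gi, "==")
  expect_lt(max(abs(q3[cross])), 0.15)  # cross-group pairs: sampling noise
})

test_that("a duplicated item is flagged and its copy removed", {
  b <- bank_recovery()
  th <- generate_thetas(500, 3, seed = 83)
  X <- simulate_responses(th, b, seed = 84)
  dup <- transform(b$items[3, ], item_id = "dup")
  b2 <- item_bank(rbind(b$items, dup), G = 2L)
  X2 <- cbind(X, dup = X[, 3])
  q3 <- q3_matrix(X2, b2)
  expect_gt(q3[3, 21], 0.2)
  scr <- screen_local_dependence(q3, b2)
  expect_true(nrow(scr$flagged) >= 1)
  expect_true("dup" %in% scr$removed || b2$items$item_id[3] %in% scr$removed)
  # every flagged pair loses at least one member
  for (r in seq_len(nrow(scr$flagged)))
    expect_true(scr$flagged$item_i[r] %in% scr$removed ||
                  scr$flagged$item_j[r] %in% scr$removed)
})

test_that("greedy screening resolves pairs by information, skipping settled ones", {
  # two flagged pairs sharing an item: (a,b) then (b,c); dropping b settles both
  df <- data.frame(item_id = c("a", "b", "c"), group_index = 0L,
                   n_categories = 2L,
                   a_general = c(2.0, 1.0, 1.5), a_group = 0, d1 = 0)
  b <- item_bank(df, G = 0L)
  q3 <- matrix(NA_real_, 3, 3)
  q3[1, 2] <- q3[2, 1] <- 0.5
  q3[2, 3] <- q3[3, 2] <- 0.3
  scr <- screen_local_dependence(q3, b)
  expect_equal(scr$removed, "b")        # lower info in the top pair
  expect_equal(scr$kept, c("a", "c"))
  # tied Q3 values resolve identically regardless of input order
  q3b <- q3; q3b[2, 3] <- q3b[3, 2] <- 0.5
  expect_equal(screen_local_dependence(q3b, b)$removed, "b")
})

test_that("scalar information responds to slopes and intercept location", {
  df <- data.frame(item_id = c("zero", "base", "double", "tail"),
                   group_index = 0L, n_categories = 2L,
                   a_general = c(1e-3, 1, 2, 1), a_group = 0,
                   d1 = c(0, 0, 0, -5))
  b <- item_bank(df, G = 0L)
  i0 <- item_information_scalar(b, "zero")
  expect_lt(i0, 1e-5)
  expect_gt(item_information_scalar(b, "double"),
            item_information_scalar(b, "base"))
  expect_gt(item_information_scalar(b, "base"),
            item_information_scalar(b, "tail"))
})

test_that("srmsr is near zero for model data and inflates under dependence", {
  b <- bank_recovery()
  th <- generate_thetas(2000, 3, seed = 91)
  X <- simulate_responses(th, b, seed = 92)
  s_clean <- srmsr(X, b)
  expect_gte(s_clean, 0)
  expect_lt(s_clean, 0.03)
  Xd <- X; Xd[, 2] <- X[, 1]            # hard dependence between items 1, 2
  expect_gt(srmsr(Xd, b), s_clean)
})
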