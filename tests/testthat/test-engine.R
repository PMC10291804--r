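test_that("determinant rule picks the dominating item and breaks ties low", {
  b <- bank_small()
  st <- posterior_state(b)
  # single candidate after administering the rest
  st$administered <- 1:4
  expect_equal(select_next_item(st, b), "s5")

  # two candidates identical except uniformly larger slopes
  df <- data.frame(item_id = c("lo", "hi"), group_index = c(1L, 1L),
                   n_categories = 3L, a_general = c(1, 2),
                   a_group = c(0.5, 1), d1 = 1, d2 = -1)
  b2 <- item_bank(df, G = 1L)
  st2 <- posterior_state(b2)
  expect_equal(select_next_item(st2, b2), "hi")
  pick <- oracle_select_det(b2, rep(NA_integer_, 2), numeric(2), 1:2)
  expect_equal(pick, 2L)
})

test_that("the starting item is shared by every respondent", {
  b <- generate_item_bank(bank_spec(), seed = 3)
  th <- generate_thetas(8, b$D, seed = 4)
  X <- simulate_responses(th, b, seed = 5)
  runs <- run_design(table3_design()["sim3"], b, X)
  firsts <- vapply(runs$records$sim3, function(r) r$items[1], character(1))
  expect_length(unique(firsts), 1L)
  expect_equal(firsts[1], select_next_item(posterior_state(b), b))
})

test_that("termination logic reproduces the factorial rules", {
  mkstate <- function(se, hist) {
    st <- posterior_state(bank_small())
    st$administered <- seq_len(nrow(hist))
    st$se <- se
    st$theta_history <- hist
    st
  }
  # general-only SE rule fires
  st <- mkstate(c(0.30, 0.9, 0.9), rbind(c(0, 0, 0)))
  dec <- check_termination(st, termination_policy(se_general = 0.32), 44)
  expect_true(dec$stop); expect_equal(dec$reason, "se_rule")
  # group rule blocks the stop even when the general SE is fine
  dec <- check_termination(st, termination_policy(se_general = 0.32,
                                                  se_group = 0.50), 44)
  expect_false(dec$stop)
  # change rule fires on its own when the SE rule does not
  st <- mkstate(c(0.50, 0.9, 0.9),
                rbind(c(0.10, 0, 0), c(0.105, 0.001, 0)))
  dec <- check_termination(st, termination_policy(se_general = 0.32,
                                                  theta_change = 0.01), 44)
  expect_true(dec$stop); expect_equal(dec$reason, "change_rule")
  # change rule needs two administered items
  st1 <- mkstate(c(0.50, 0.9, 0.9), rbind(c(0.10, 0, 0)))
  dec <- check_termination(st1, termination_policy(se_general = 0.32,
                                                   theta_change = 0.01), 44)
  expect_false(dec$stop)
  # thresholds are strict
  st <- mkstate(c(0.32, 0.9, 0.9), rbind(c(0, 0, 0)))
  dec <- check_termination(st, termination_policy(se_general = 0.32), 44)
  expect_false(dec$stop)
  expect_error(termination_policy(se_general = -1), "positive")
})

test_that("the bundled design encodes the 2x2x2 factorial plus the full row", {
  d <- table3_design()
  expect_named(d, c("full", paste0("sim", 1:8)))
  expect_null(d$full$se_general)
  expect_equal(vapply(d[paste0("sim", 1:4)], `[[`, numeric(1), "se_general"),
               rep(0.32, 4), ignore_attr = TRUE)
  expect_equal(vapply(d[paste0("sim", 5:8)], `[[`, numeric(1), "se_general"),
               rep(0.40, 4), ignore_attr = TRUE)
  for (nm in c("sim1", "sim2", "sim5", "sim6"))
    expect_equal(d[[nm]]$se_group, 0.50)
  for (nm in c("sim3", "sim4", "sim7", "sim8"))
    expect_null(d[[nm]]$se_group)
  for (nm in c("sim2", "sim4", "sim6", "sim8"))
    expect_equal(d[[nm]]$theta_change, 0.01)
})

test_that("a full run administers everything and matches batch MAP", {
  b <- generate_item_bank(bank_spec(), seed = 3)
  th <- generate_thetas(6, b$D, seed = 14)
  X <- simulate_responses(th, b, seed = 15)
  for (j in 1:6) {
    rec <- administer_respondent(X[j, ], b, termination_policy())
    expect_equal(rec$n_items, 44L)
    expect_equal(rec$stop_reason, "exhausted")
    expect_false(anyDuplicated(rec$items) > 0)
    expect_equal(rec$theta, map_estimate(b, X[j, ]), tolerance = 1e-6)
  }
})

test_that("the engine is deterministic and selection matches brute force", {
  b <- bank_recovery()
  th <- generate_thetas(10, b$D, seed = 41)
  X <- simulate_responses(th, b, seed = 42)
  pol <- termination_policy(se_general = 0.40, name = "chk")
  r1 <- run_design(list(chk = pol), b, X)
  r2 <- run_design(list(chk = pol), b, X)
  expect_identical(r1$records, r2$records)

  # replay each administration, checking every pick against full
  # determinant enumeration (and thereby the rank-1 update identity)
  ids <- b$items$item_id
  for (j in 1:10) {
    rec <- r1$records$chk[[j]]
    seq_idx <- match(rec$items, ids)
    for (t in seq_along(seq_idx)[-1]) {
      pat <- rep(NA_integer_, n_items(b))
      pat[seq_idx[seq_len(t - 1)]] <- rec$responses[seq_len(t - 1)]
      tht <- map_estimate(b, pat)
      cand <- setdiff(seq_len(n_items(b)), seq_idx[seq_len(t - 1)])
      expect_equal(seq_idx[t], oracle_select_det(b, pat, tht, cand))
    }
  }
})

test_that("a binding group-SE rule forces weakly longer administrations", {
  b <- generate_item_bank(bank_spec(), seed = 3)
  th <- generate_thetas(8, b$D, seed = 24)
  X <- simulate_responses(th, b, seed = 25)
  runs <- run_design(table3_design()[c("sim1", "sim3")], b, X)
  n1 <- vapply(runs$records$sim1, `[[`, numeric(1), "n_items")
  n3 <- vapply(runs$records$sim3, `[[`, numeric(1), "n_items")
  expect_true(all(n1 >= n3))
})
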