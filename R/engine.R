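# ---- The MCAT loop: D-rule selection, stopping rules, batch simulation ----
#
# The engine is fully deterministic: all randomness lives in the synthetic
# response generator. Responses to the complete bank are pre-simulated and
# the engine merely reveals them item by item.

#' Termination policy for an adaptive administration
#'
#' Stopping is checked after every response/rescoring step. The SE rule is
#' satisfied when every supplied SE threshold holds strictly: the general
#' factor SE below `se_general` and (when `se_group` is given) the SE of
#' every group dimension below `se_group`. The theta-change rule is
#' satisfied when at least two items have been administered and the largest
#' absolute change of any trait estimate from the previous step falls
#' strictly below `theta_change`. Administration stops when the SE rule, the
#' change rule, or item exhaustion fires, whichever comes first.
#'
#' @param se_general,se_group,theta_change positive thresholds, or `NULL`
#'   to disable that criterion.
#' @param max_items administration cap (defaults to the bank size at run
#'   time).
#' @param name optional label.
#' @return a `termination_policy` object.
#' @export
termination_policy <- function(se_general = NULL, se_group = NULL,
                               theta_change = NULL, max_items = NULL,
                               name = NULL) {
  for (v in list(se_general, se_group, theta_change))
    if (!is.null(v) && (!is.numeric(v) || v <= 0))
      stop("thresholds must be positive")
  structure(list(se_general = se_general, se_group = se_group,
                 theta_change = theta_change, max_items = max_items,
                 name = name),
            class = "termination_policy")
}

#' The bundled 2 x 2 x 2 factorial stopping-rule design
#'
#' Nine rows: a "full" run with no stopping criteria (every item is
#' administered, adaptively ordered), followed by the eight crossings of
#' general-factor SE threshold (0.32 / 0.40), group-factor SE threshold
#' (0.50 / none), and theta-change threshold (0.01 / none). The 0.32 / 0.40
#' general thresholds correspond to reliabilities 0.90 / 0.85 and the 0.50
#' group threshold to 0.75 under `reliability = 1 - SE^2`.
#'
#' @return a named list of [termination_policy()] rows, class
#'   `simulation_design`.
#' @export
table3_design <- function() {
  pol <- function(...) termination_policy(...)
  structure(list(
    full = pol(name = "full"),
    sim1 = pol(se_general = 0.32, se_group = 0.50, name = "sim1"),
    sim2 = pol(se_general = 0.32, se_group = 0.50, theta_change = 0.01,
               name = "sim2"),
    sim3 = pol(se_general = 0.32, name = "sim3"),
    sim4 = pol(se_general = 0.32, theta_change = 0.01, name = "sim4"),
    sim5 = pol(se_general = 0.40, se_group = 0.50, name = "sim5"),
    sim6 = pol(se_general = 0.40, se_group = 0.50, theta_change = 0.01,
               name = "sim6"),
    sim7 = pol(se_general = 0.40, name = "sim7"),
    sim8 = pol(se_general = 0.40, theta_change = 0.01, name = "sim8")),
    class = "simulation_design")
}

#' Empty posterior state for one respondent
#'
#' Holds the running MAP estimate, the posterior information matrix
#' (prior-only identity at the start), standard errors, and the
#' administration history.
#'
#' @param bank an [item_bank()].
#' @return a `posterior_state` object.
#' @export
posterior_state <- function(bank) {
  D <- bank$D
  structure(list(theta = numeric(D), info = diag(D), se = rep(1, D),
                 administered = integer(0), responses = integer(0),
                 theta_history = matrix(numeric(0), 0L, D)),
            class = "posterior_state")
}

# index of the determinant-rule pick among unadministered items
.select_index <- function(arr, state) {
  cand <- setdiff(seq_len(arr$n), state$administered)
  if (!length(cand)) stop("no unadministered items left")
  w <- bank_info_weights(arr, state$theta)
  Minv <- chol2inv(chol(state$info))
  a0 <- arr$a0[cand]; ag <- arr$ag[cand]; gi <- arr$gi[cand]
  gd <- gi + 1L
  qf <- a0^2 * Minv[1L, 1L] +
    ifelse(gi > 0L,
           2 * a0 * ag * Minv[cbind(1L, pmax(gd, 1L))] +
             ag^2 * Minv[cbind(pmax(gd, 1L), pmax(gd, 1L))],
           0)
  crit <- w[cand] * qf          # det ratio - 1; monotone in the determinant
  cand[which.max(crit)]         # which.max takes the first (lowest index) tie
}

#' Determinant-rule (D-optimal) item selection
#'
#' Scores every unadministered item by the determinant of the posterior
#' information matrix it would produce if added at the current trait
#' estimate, `det(info + w_i a_i a_i')`, and returns the maximizer. Via the
#' rank-1 identity this equals `det(info) (1 + w_i a_i' info^-1 a_i)`, so
#' only a quadratic form per candidate is evaluated. On an empty state
#' (prior-only information, theta = 0) the pick is the study's fixed
#' starting item, identical for every respondent. Ties go to the lowest
#' item index.
#'
#' @param state a [posterior_state()].
#' @param bank the [item_bank()].
#' @return the selected `item_id`.
#' @export
select_next_item <- function(state, bank) {
  bank$items$item_id[.select_index(bank_arrays(bank), state)]
}

#' Check a stopping policy against the current state
#'
#' @param state a [posterior_state()] with at least one administered item.
#' @param policy a [termination_policy()].
#' @param bank_size total bank size, for the exhaustion check.
#' @return list with `stop` (logical) and `reason` (`"se_rule"`,
#'   `"change_rule"`, `"exhausted"`, or `NA` when continuing).
#' @export
check_termination <- function(state, policy, bank_size = Inf) {
  m <- length(state$administered)
  stopifnot(m >= 1L)
  se_rule <- FALSE
  if (!is.null(policy$se_general) || !is.null(policy$se_group)) {
    ok_gen <- is.null(policy$se_general) || state$se[1L] < policy$se_general
    ok_grp <- is.null(policy$se_group) ||
      all(state$se[-1L] < policy$se_group)
    se_rule <- ok_gen && ok_grp
  }
  change_rule <- FALSE
  if (!is.null(policy$theta_change) && m >= 2L) {
    h <- state$theta_history
    change_rule <- max(abs(h[nrow(h), ] - h[nrow(h) - 1L, ])) <
      policy$theta_change
  }
  max_items <- if (is.null(policy$max_items)) bank_size else policy$max_items
  exhausted <- m >= min(max_items, bank_size)
  if (se_rule) list(stop = TRUE, reason = "se_rule")
  else if (change_rule) list(stop = TRUE, reason = "change_rule")
  else if (exhausted) list(stop = TRUE, reason = "exhausted")
  else list(stop = FALSE, reason = NA_character_)
}

#' Adaptively administer one respondent
#'
#' Runs the select / respond / rescore / check loop against a pre-simulated
#' complete response vector: the determinant rule picks the next item, the
#' stored response is revealed, the MAP estimate and posterior information
#' are refreshed on the administered subset, and the policy is checked.
#' Deterministic given `(true_responses, bank, policy)`.
#'
#' @param true_responses complete 0-based response vector over the bank.
#' @param bank an [item_bank()].
#' @param policy a [termination_policy()].
#' @param store_history keep the per-step trait trajectory in the record.
#' @return an `administration_record`: list with `items` (ids in
#'   administration order), `responses`, `theta`, `se`, `n_items`,
#'   `stop_reason`, and (optionally) `theta_history`.
#' @export
administer_respondent <- function(true_responses, bank, policy,
                                  store_history = FALSE) {
  arr <- bank_arrays(bank)
  .administer(arr, as.integer(true_responses), policy, store_history)
}

# scalar information weights w(z) for every bank item at theta, using the
# precomputed NA mask in arr (fast path for the selection rule)
.weights_fast <- function(arr, theta) {
  thlook <- c(0, theta[-1L])
  z <- arr$a0 * theta[1L] + arr$ag * thlook[arr$gi + 1L]
  Ps <- stats::plogis(z + arr$dmat)
  Ps[arr$namask] <- 0
  m <- arr$maxK
  B <- arr$Btmpl
  B[, 2:m] <- Ps[, seq_len(m - 1L), drop = FALSE]
  P <- B[, 1:m, drop = FALSE] - B[, 2:(m + 1L), drop = FALSE]
  q <- B * (1 - B)
  num <- q[, 1:m, drop = FALSE] - q[, 2:(m + 1L), drop = FALSE]
  Pf <- P
  Pf[Pf < .P_FLOOR] <- 1        # wherever P ~ 0 the numerator is 0 too
  rowSums(num * num / Pf)
}

# damped Fisher-scoring MAP restricted to the administered subset; identical
# math to .map_core, but the posterior information is kept in its "arrow"
# form (general-factor diagonal i11, group diagonals dg, coupling bg) so
# every solve and inverse is O(D) via the Schur complement
# s = i11 - sum(bg^2 / dg).
.map_fast <- function(arr, adm, cols, start, tol = 1e-8, max_iter = 60L) {
  D <- arr$D
  m <- length(adm)
  a0s <- arr$a0[adm]; ags <- arr$ag[adm]; gis <- arr$gi[adm]
  dsub <- arr$dmat[adm, , drop = FALSE]
  nas <- is.na(dsub)
  maxK <- arr$maxK
  rows_i <- seq_len(m)
  lin <- rows_i + m * (cols - 1L)          # linear indices into m x * grids
  lin1 <- lin + m
  pos <- which(gis > 0L)
  groups <- unique(gis[pos])
  glist <- lapply(groups, function(g) which(gis == g))
  a0ag <- a0s * ags
  ag2 <- ags^2
  a02 <- a0s^2
  pieces <- function(theta) {
    thlook <- c(0, theta[-1L])
    z <- a0s * theta[1L] + ags * thlook[gis + 1L]
    Ps <- stats::plogis(z + dsub)
    Ps[nas] <- 0
    B <- matrix(0, m, maxK + 1L); B[, 1L] <- 1
    B[, 2:maxK] <- Ps[, seq_len(maxK - 1L), drop = FALSE]
    P <- B[, 1:maxK, drop = FALSE] - B[, 2:(maxK + 1L), drop = FALSE]
    q <- B * (1 - B)
    Pk <- P[lin]; Pk[Pk < .P_FLOOR] <- .P_FLOOR
    s <- (q[lin] - q[lin1]) / Pk
    num <- q[, 1:maxK, drop = FALSE] - q[, 2:(maxK + 1L), drop = FALSE]
    Pf <- P; Pf[Pf < .P_FLOOR] <- 1
    w <- rowSums(num * num / Pf)
    grad <- -theta
    grad[1L] <- grad[1L] + sum(a0s * s)
    i11 <- 1 + sum(w * a02)
    bg <- numeric(D - 1L); dg <- rep(1, D - 1L)
    for (k in seq_along(groups)) {
      v <- glist[[k]]; g <- groups[k]
      grad[g + 1L] <- grad[g + 1L] + sum(ags[v] * s[v])
      bg[g] <- sum(w[v] * a0ag[v])
      dg[g] <- 1 + sum(w[v] * ag2[v])
    }
    list(grad = grad, i11 = i11, bg = bg, dg = dg,
         lp = sum(log(Pk)) - 0.5 * sum(theta^2))
  }
  # cheap evaluation of gradient and log-posterior only: each item needs just
  # its picked category's two boundary curves, not the whole category grid
  dlow <- rep(Inf, m); j <- which(cols > 1L)
  dlow[j] <- dsub[cbind(j, cols[j] - 1L)]
  Ki <- arr$K[adm]
  dhigh <- rep(-Inf, m); j <- which(cols < Ki)
  dhigh[j] <- dsub[cbind(j, cols[j])]
  gradeval <- function(theta) {
    thlook <- c(0, theta[-1L])
    z <- a0s * theta[1L] + ags * thlook[gis + 1L]
    Plow <- stats::plogis(z + dlow)
    Phigh <- stats::plogis(z + dhigh)
    Pk <- Plow - Phigh; Pk[Pk < .P_FLOOR] <- .P_FLOOR
    s <- (Plow * (1 - Plow) - Phigh * (1 - Phigh)) / Pk
    grad <- -theta
    grad[1L] <- grad[1L] + sum(a0s * s)
    for (k in seq_along(groups)) {
      v <- glist[[k]]; g <- groups[k]
      grad[g + 1L] <- grad[g + 1L] + sum(ags[v] * s[v])
    }
    list(grad = grad, lp = sum(log(Pk)) - 0.5 * sum(theta^2))
  }
  arrow_solve <- function(pc, r) {
    schur <- pc$i11 - sum(pc$bg^2 / pc$dg)
    x1 <- (r[1L] - sum(pc$bg * r[-1L] / pc$dg)) / schur
    c(x1, (r[-1L] - pc$bg * x1) / pc$dg)
  }
  theta <- start
  # Fisher information at the warm start serves as a frozen preconditioner;
  # refreshed if convergence drags (theta barely moves between items, so the
  # frozen matrix is near-exact and the iteration stays quadratic-ish)
  precond <- pieces(theta)
  pcg <- list(grad = precond$grad, lp = precond$lp)
  for (iter in seq_len(max_iter)) {
    if (max(abs(pcg$grad)) < tol) {
      pc <- pieces(theta)        # exact information at the converged theta
      schur <- pc$i11 - sum(pc$bg^2 / pc$dg)
      se <- sqrt(c(1 / schur, 1 / pc$dg + pc$bg^2 / (pc$dg^2 * schur)))
      return(list(theta = theta, se = se, i11 = pc$i11, bg = pc$bg,
                  dg = pc$dg, schur = schur))
    }
    if (iter %% 8L == 0L) precond <- pieces(theta)
    step <- arrow_solve(precond, pcg$grad)
    lambda <- 1
    repeat {
      cand <- pmin(pmax(theta + lambda * step, -6), 6)
      pc2 <- gradeval(cand)
      if (pc2$lp >= pcg$lp - 1e-12 || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    theta <- cand; pcg <- pc2
  }
  # fall back to the reference implementation on the rare hard pattern
  fit <- .map_core(arr, adm, cols - 1L, start = start, tol = tol)
  info <- fit$info
  bg <- info[1L, -1L]; dg <- diag(info)[-1L]
  schur <- info[1L, 1L] - sum(bg^2 / dg)
  list(theta = fit$theta, se = standard_errors(info),
       i11 = info[1L, 1L], bg = bg, dg = dg, schur = schur)
}

.administer <- function(arr, x, policy, store_history = FALSE,
                        first_item = NULL) {
  if (length(x) != arr$n) stop("true_responses must cover the whole bank")
  D <- arr$D
  chk_se <- !is.null(policy$se_general) || !is.null(policy$se_group)
  chk_ch <- !is.null(policy$theta_change)
  max_items <- min(if (is.null(policy$max_items)) arr$n else policy$max_items,
                   arr$n)
  theta <- numeric(D)
  # arrow form of the posterior information; prior-only at the start
  inv11 <- 1; inv1g <- numeric(D - 1L); invgg <- rep(1, D - 1L)
  adm <- integer(0); resp <- integer(0)
  hist <- matrix(0, arr$n, D)
  reason <- "exhausted"
  se <- rep(1, D)
  repeat {
    m <- length(adm)
    nxt <- if (m == 0L && !is.null(first_item)) first_item
      else {
        cand <- if (m == 0L) seq_len(arr$n) else seq_len(arr$n)[-adm]
        w <- .weights_fast(arr, theta)
        a0 <- arr$a0[cand]; ag <- arr$ag[cand]
        gx <- pmax(arr$gi[cand], 1L)      # ag = 0 kills the bogus lookup
        qf <- a0^2 * inv11 + 2 * a0 * ag * inv1g[gx] + ag^2 * invgg[gx]
        cand[which.max(w[cand] * qf)]
      }
    adm <- c(adm, nxt)
    resp <- c(resp, x[nxt])
    m <- m + 1L
    fit <- .map_fast(arr, adm, resp + 1L, start = theta)
    theta <- fit$theta
    se <- fit$se
    inv11 <- 1 / fit$schur
    inv1g <- -fit$bg / (fit$dg * fit$schur)
    invgg <- 1 / fit$dg + fit$bg^2 / (fit$dg^2 * fit$schur)
    hist[m, ] <- theta
    stop_now <- FALSE
    if (chk_se) {
      ok_gen <- is.null(policy$se_general) || se[1L] < policy$se_general
      ok_grp <- is.null(policy$se_group) || all(se[-1L] < policy$se_group)
      if (ok_gen && ok_grp) { stop_now <- TRUE; reason <- "se_rule" }
    }
    if (!stop_now && chk_ch && m >= 2L &&
        max(abs(hist[m, ] - hist[m - 1L, ])) < policy$theta_change) {
      stop_now <- TRUE; reason <- "change_rule"
    }
    if (!stop_now && m >= max_items) { stop_now <- TRUE; reason <- "exhausted" }
    if (stop_now) break
  }
  rec <- list(items = arr$ids[adm], responses = resp,
              theta = theta, se = se,
              n_items = length(adm), stop_reason = reason)
  if (store_history) rec$theta_history <- hist[seq_along(adm), , drop = FALSE]
  structure(rec, class = "administration_record")
}

#' Run a full stopping-rule design over a respondent sample
#'
#' Administers every respondent under every design row. The engine draws no
#' random numbers: identical inputs give identical outputs. The starting
#' item (determinant rule at the prior state) is computed once and shared
#' by all respondents.
#'
#' @param design a [table3_design()]-style named list of policies.
#' @param bank an [item_bank()].
#' @param responses complete persons x items matrix of pre-simulated 0-based
#'   responses ([simulate_responses()]).
#' @param store_history keep per-step trait trajectories.
#' @param verbose print one line per design row.
#' @return class `mcat_runs`: list with `records` (per design row, a list of
#'   `administration_record`s), `design`, and the bank's item ids.
#' @export
run_design <- function(design, bank, responses, store_history = FALSE,
                       verbose = FALSE) {
  X <- as.matrix(responses)
  if (ncol(X) != n_items(bank))
    stop("responses and bank have different item counts")
  if (anyNA(X)) stop("engine inputs must be complete response vectors")
  arr <- bank_arrays(bank)
  empty <- list(theta = numeric(arr$D), info = diag(arr$D),
                administered = integer(0))
  first_item <- .select_index(arr, empty)
  records <- lapply(design, function(policy) {
    t0 <- Sys.time()
    out <- lapply(seq_len(nrow(X)), function(j)
      .administer(arr, as.integer(X[j, ]), policy, store_history,
                  first_item = first_item))
    if (verbose)
      message(sprintf("%-6s mean items %.1f  (%.1fs)",
                      if (is.null(policy$name)) "row" else policy$name,
                      mean(vapply(out, `[[`, numeric(1), "n_items")),
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  })
  structure(list(records = records, design = design,
                 item_ids = bank$items$item_id, D = bank$D),
            class = "mcat_runs")
}

#' @export
print.mcat_runs <- function(x, ...) {
  cat(sprintf("MCAT runs: %d design row(s) x %d respondent(s)\n",
              length(x$records), length(x$records[[1L]])))
  for (nm in names(x$records)) {
    ni <- vapply(x$records[[nm]], `[[`, numeric(1), "n_items")
    cat(sprintf("  %-5s median items %4.0f (mean %.1f)\n", nm,
                stats::median(ni), mean(ni)))
  }
  invisible(x)
}
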