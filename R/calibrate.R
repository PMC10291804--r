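# ---- Full-information ML calibration of the bifactor GRM ----
#
# Bock-Aitkin EM with the bifactor dimension reduction: because every item
# loads on the general dimension and at most one group dimension, the
# marginal person likelihood factors as
#   L_j = int phi(t0) prod_g [ int phi(tg) prod_{i in g} P_i(t0, tg) dtg ] dt0
# so only two-dimensional quadrature grids are ever needed, regardless of G.

.quad_grid <- function(n_quad = 21L, range = c(-6, 6)) {
  q <- seq(range[1], range[2], length.out = n_quad)
  w <- stats::dnorm(q)
  list(q = q, w = w / sum(w))
}

# K x m matrix of category probabilities for one item's parameters on a grid
# of linear predictors z (length m)
.item_prob_grid <- function(a0, ag, d, t0, tg) {
  z <- a0 * t0 + if (is.null(tg)) 0 else ag * tg
  Pb <- t(vapply(d, function(dk) stats::plogis(z + dk), numeric(length(z))))
  Pstar <- rbind(1, Pb, 0)
  K <- length(d) + 1L
  Pstar[seq_len(K), , drop = FALSE] - Pstar[seq_len(K) + 1L, , drop = FALSE]
}

# M-step objective/gradient for one item on its quadrature grid.
# Parameter vector phi = (a0 [, ag], d1 [, t_2..t_{K-1}]) with
# d_k = d1 - cumsum(exp(t_k)) enforcing strictly decreasing intercepts.
.phi_unpack <- function(phi, grouped, K) {
  a0 <- phi[1L]
  ag <- if (grouped) phi[2L] else 0
  off <- 1L + grouped
  d1 <- phi[off + 1L]
  d <- d1
  if (K > 2L) d <- d1 - cumsum(c(0, exp(phi[(off + 2L):(off + K - 1L)])))
  list(a0 = a0, ag = ag, d = d)
}

.phi_pack <- function(a0, ag, d, grouped) {
  K <- length(d) + 1L
  t <- if (K > 2L) log(pmax(-diff(d), 1e-6)) else NULL
  c(a0, if (grouped) ag, d[1L], t)
}

.mstep_item <- function(phi0, r, t0, tg, grouped, K, control = list()) {
  negloglik <- function(phi) {
    p <- .phi_unpack(phi, grouped, K)
    P <- .item_prob_grid(p$a0, p$ag, p$d, t0, tg)
    -sum(r * log(pmax(P, .P_FLOOR)))
  }
  neggrad <- function(phi) {
    p <- .phi_unpack(phi, grouped, K)
    z <- p$a0 * t0 + if (grouped) p$ag * tg else 0
    Pstar <- rbind(1, t(vapply(p$d, function(dk) stats::plogis(z + dk),
                               numeric(length(z)))), 0)
    q <- Pstar * (1 - Pstar)
    P <- pmax(Pstar[seq_len(K), , drop = FALSE] -
                Pstar[seq_len(K) + 1L, , drop = FALSE], .P_FLOOR)
    rat <- r / P                               # K x m
    gz <- colSums(rat * (q[seq_len(K), , drop = FALSE] -
                           q[seq_len(K) + 1L, , drop = FALSE]))
    # boundary gradient of f: df/dd_m = sum_nodes q_m (rat[m+1,] - rat[m,])
    gd <- vapply(seq_len(K - 1L), function(m)
      sum(q[m + 1L, ] * (rat[m + 1L, ] - rat[m, ])), numeric(1))
    ga0 <- sum(gz * t0)
    gag <- if (grouped) sum(gz * tg) else NULL
    gd1 <- sum(gd)
    gt <- if (K > 2L) {
      off <- 1L + grouped
      tpar <- phi[(off + 2L):(off + K - 1L)]
      vapply(2:(K - 1L), function(j) -exp(tpar[j - 1L]) * sum(gd[j:(K - 1L)]),
             numeric(1))
    } else NULL
    -c(ga0, gag, gd1, gt)
  }
  lower <- rep(-Inf, length(phi0)); upper <- rep(Inf, length(phi0))
  lower[1L] <- 1e-3; upper[1L] <- 25
  if (grouped) { lower[2L] <- -25; upper[2L] <- 25 }
  opt <- stats::optim(phi0, negloglik, neggrad, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = c(list(maxit = 50L), control))
  if (opt$value > negloglik(phi0) + 1e-10) return(phi0)  # never step downhill
  opt$par
}

.parse_structure <- function(structure, item_ids) {
  if (is.data.frame(structure)) {
    idx <- match(item_ids, as.character(structure[[1L]]))
    if (anyNA(idx))
      stop("structure lacks items: ",
           paste(item_ids[is.na(idx)], collapse = ", "))
    gi <- as.integer(structure[[2L]][idx])
  } else {
    if (is.null(names(structure)))
      gi <- as.integer(structure)
    else {
      idx <- match(item_ids, names(structure))
      if (anyNA(idx))
        stop("structure lacks items: ",
             paste(item_ids[is.na(idx)], collapse = ", "))
      gi <- as.integer(structure[idx])
    }
  }
  if (length(gi) != length(item_ids)) stop("structure length mismatch")
  if (any(gi < 0L)) stop("group indices must be >= 0")
  gi
}

# collapse categories never observed in the data into the adjacent lower
# category; returns remapped x (0-based) and the new K
.collapse_unobserved <- function(x, K, item_id, action = "collapse") {
  obs <- sort(unique(x[!is.na(x)]))
  if (length(obs) < 2L)
    stop("item ", item_id, ": fewer than 2 observed categories")
  if (length(obs) == K && all(obs == 0:(K - 1L))) return(list(x = x, K = K))
  if (action == "error")
    stop("item ", item_id, ": unobserved response categories")
  warning("item ", item_id, ": collapsing ", K - length(obs),
          " unobserved categor", if (K - length(obs) == 1L) "y" else "ies",
          call. = FALSE)
  list(x = match(x, obs) - 1L, K = length(obs))
}

#' Fit a bifactor graded response model by full-information ML
#'
#' Marginal maximum likelihood via Bock-Aitkin EM with the bifactor
#' dimension reduction, so only two-dimensional quadrature is required per
#' group factor. Missing responses are handled by full information: they
#' simply drop out of the person likelihood, no imputation. The returned
#' object is the package's central model fit; its `$bank` drives scoring,
#' local-dependence screening and the adaptive engine.
#'
#' @param responses integer matrix (persons x items) of 0-based categories,
#'   `NA` for missing; columns named with item ids.
#' @param structure item-to-group-factor assignment: a named integer vector
#'   (`0` = loads on the general factor only) or a two-column data frame
#'   `(item_id, group_index)`.
#' @param n_categories optional integer vector of category counts per item;
#'   defaults to `max + 1` observed per column.
#' @param n_quad quadrature points per dimension (equally spaced on
#'   `quad_range`, normal-density weights renormalized).
#' @param quad_range quadrature support.
#' @param max_cycles EM cycle cap; exceeding it flags non-convergence.
#' @param tol_param,tol_loglik convergence tolerances: EM stops when the
#'   largest absolute parameter change or the log-likelihood change falls
#'   below these.
#' @param unobserved `"collapse"` (merge never-observed categories downward,
#'   with a warning) or `"error"`.
#' @param verbose print per-cycle log-likelihoods.
#' @return an object of class `bfgrm` with elements `bank` (the calibrated
#'   [item_bank()]), `loglik` (per-cycle observed-data log-likelihood
#'   trajectory), `converged`, `n_cycles`, `n_persons`, and `settings`.
#' @export
bfgrm <- function(responses, structure, n_categories = NULL,
                  n_quad = 21L, quad_range = c(-6, 6), max_cycles = 500L,
                  tol_param = 1e-4, tol_loglik = 1e-6,
                  unobserved = c("collapse", "error"), verbose = FALSE) {
  unobserved <- match.arg(unobserved)
  X <- as.matrix(responses)
  if (is.null(colnames(X))) colnames(X) <- sprintf("item%02d", seq_len(ncol(X)))
  ids <- colnames(X)
  J <- ncol(X); n <- nrow(X)
  gi <- .parse_structure(structure, ids)
  G <- max(gi, 0L)
  if (is.null(n_categories))
    n_categories <- apply(X, 2L, function(x) max(x, na.rm = TRUE) + 1L)
  K <- as.integer(n_categories)
  if (any(colSums(!is.na(X)) < 2L)) stop("every item needs >= 2 responses")
  for (j in seq_len(J)) {
    if (any(X[, j] < 0L | X[, j] >= K[j], na.rm = TRUE))
      stop("item ", ids[j], ": responses outside 0..K-1")
    cl <- .collapse_unobserved(X[, j], K[j], ids[j], unobserved)
    X[, j] <- cl$x; K[j] <- cl$K
  }

  qd <- .quad_grid(n_quad, quad_range)
  m1 <- n_quad                      # 1-D grid size
  m2 <- n_quad^2                    # 2-D grid size (q0 slow, qg fast)
  t0_2 <- rep(qd$q, each = m1)
  tg_2 <- rep(qd$q, times = m1)
  wg_2 <- rep(qd$w, times = m1)     # conditional weight over the group dim
  blk <- rep(seq_len(m1), each = m1)
  Smat <- outer(blk, seq_len(m1), "==") * 1   # m2 x m1 block collapser

  # initial parameters
  a0 <- rep(1, J)
  ag <- ifelse(gi > 0L, 0.5, 0)
  dlist <- vector("list", J)
  for (j in seq_len(J)) {
    x <- X[, j]
    pr <- vapply(seq_len(K[j] - 1L),
                 function(k) mean(x >= k, na.rm = TRUE), numeric(1))
    d <- stats::qlogis(pmin(pmax(pr, 0.01), 0.99))
    d <- d - seq_along(d) * 1e-3              # break exact ties, keep order
    dlist[[j]] <- rev(sort(d))
  }

  grp_items <- split(seq_len(J), factor(gi, levels = 0:G))
  gen_items <- grp_items[["0"]]
  trajectory <- numeric(0)
  converged <- FALSE
  par_flat <- function() unlist(c(a0, ag, dlist))
  old_par <- par_flat()

  for (cycle in seq_len(max_cycles)) {
    # --- E step: likelihood pieces ---
    # per-group n x m2 products and collapsed n x m1 integrals
    Mg <- vector("list", G)
    Lg <- vector("list", G)
    for (g in seq_len(G)) {
      items <- grp_items[[as.character(g)]]
      M <- matrix(1, n, m2)
      for (j in items) {
        P <- .item_prob_grid(a0[j], ag[j], dlist[[j]], t0_2, tg_2)
        Paug <- rbind(P, 1)
        idx <- ifelse(is.na(X[, j]), K[j] + 1L, X[, j] + 1L)
        M <- M * Paug[idx, , drop = FALSE]
      }
      Mg[[g]] <- M
      Lg[[g]] <- sweep(M, 2L, wg_2, "*") %*% Smat
    }
    Lgen <- matrix(1, n, m1)
    for (j in gen_items) {
      P <- .item_prob_grid(a0[j], 0, dlist[[j]], qd$q, NULL)
      Paug <- rbind(P, 1)
      idx <- ifelse(is.na(X[, j]), K[j] + 1L, X[, j] + 1L)
      Lgen <- Lgen * Paug[idx, , drop = FALSE]
    }
    A <- Lgen
    for (g in seq_len(G)) A <- A * Lg[[g]]
    Lmarg <- as.numeric(A %*% qd$w)
    Lmarg <- pmax(Lmarg, 1e-300)
    ll <- sum(log(Lmarg))
    trajectory <- c(trajectory, ll)
    if (verbose) message(sprintf("cycle %3d  loglik %.6f", cycle, ll))

    # --- E step: expected category counts on each item's grid ---
    # general-only items: posterior over t0 alone
    post0 <- sweep(A, 2L, qd$w, "*") / Lmarg
    for (j in gen_items) {
      Ind <- outer(X[, j], 0:(K[j] - 1L), "==") * 1
      Ind[is.na(Ind)] <- 0
      r <- crossprod(Ind, post0)                       # K x m1
      phi0 <- .phi_pack(a0[j], 0, dlist[[j]], FALSE)
      phi <- .mstep_item(phi0, r, qd$q, NULL, FALSE, K[j])
      p <- .phi_unpack(phi, FALSE, K[j])
      a0[j] <- p$a0; dlist[[j]] <- p$d
    }
    for (g in seq_len(G)) {
      items <- grp_items[[as.character(g)]]
      Amg <- Lgen
      for (g2 in seq_len(G)) if (g2 != g) Amg <- Amg * Lg[[g2]]
      outer0 <- sweep(Amg, 2L, qd$w, "*") / Lmarg      # n x m1
      postg <- outer0[, blk, drop = FALSE] *
        sweep(Mg[[g]], 2L, wg_2, "*")                  # n x m2
      for (j in items) {
        Ind <- outer(X[, j], 0:(K[j] - 1L), "==") * 1
        Ind[is.na(Ind)] <- 0
        r <- crossprod(Ind, postg)                     # K x m2
        phi0 <- .phi_pack(a0[j], ag[j], dlist[[j]], TRUE)
        phi <- .mstep_item(phi0, r, t0_2, tg_2, TRUE, K[j])
        p <- .phi_unpack(phi, TRUE, K[j])
        a0[j] <- p$a0; ag[j] <- p$ag; dlist[[j]] <- p$d
      }
    }

    new_par <- par_flat()
    dpar <- max(abs(new_par - old_par))
    dll <- if (cycle > 1L) ll - trajectory[cycle - 1L] else Inf
    old_par <- new_par
    if (dpar < tol_param || abs(dll) < tol_loglik) { converged <- TRUE; break }
  }

  # orient each group factor so the sum of its group slopes is positive
  for (g in seq_len(G)) {
    items <- grp_items[[as.character(g)]]
    if (length(items) && sum(ag[items]) < 0) ag[items] <- -ag[items]
  }

  maxK <- max(K)
  df <- data.frame(item_id = ids, group_index = gi, n_categories = K,
                   a_general = a0, a_group = ag)
  for (k in seq_len(maxK - 1L))
    df[[paste0("d", k)]] <- vapply(dlist, function(d)
      if (length(d) >= k) d[k] else NA_real_, numeric(1))
  bank <- item_bank(df, G = G)

  structure(list(bank = bank, loglik = trajectory, converged = converged,
                 n_cycles = length(trajectory), n_persons = n,
                 settings = list(n_quad = n_quad, quad_range = quad_range,
                                 tol_param = tol_param,
                                 tol_loglik = tol_loglik,
                                 max_cycles = max_cycles),
                 call = match.call()),
            class = "bfgrm")
}

#' @export
print.bfgrm <- function(x, ...) {
  cat("Bifactor graded response model (full-information ML, EM)\n")
  cat(sprintf("  %d persons, %d items, %d group factor(s)\n",
              x$n_persons, n_items(x$bank), x$bank$G))
  cat(sprintf("  log-likelihood %.3f after %d cycle(s)%s\n",
              utils::tail(x$loglik, 1L), x$n_cycles,
              if (x$converged) "" else "  [NOT converged]"))
  invisible(x)
}

#' @export
summary.bfgrm <- function(object, ...) {
  print(object)
  cat("\nItem parameters:\n")
  print(coef(object), digits = 3)
  invisible(object)
}

#' @export
coef.bfgrm <- function(object, ...) object$bank$items

#' @export
logLik.bfgrm <- function(object, ...) {
  val <- utils::tail(object$loglik, 1L)
  it <- object$bank$items
  npar <- sum(it$n_categories - 1L) + nrow(it) + sum(it$group_index > 0L)
  structure(val, df = npar, nobs = object$n_persons, class = "logLik")
}

#' @export
predict.bfgrm <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  t(apply(X, 1L, function(x) map_estimate(object$bank, as.integer(x))))
}

#' @export
simulate.bfgrm <- function(object, nsim = 1, seed = NULL, thetas = NULL, ...) {
  if (is.null(thetas))
    thetas <- generate_thetas(nsim, object$bank$D, seed = seed)
  simulate_responses(thetas, object$bank, seed = seed)
}

#' @export
residuals.bfgrm <- function(object, newdata, ...) {
  grm_residuals(newdata, object$bank)
}
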