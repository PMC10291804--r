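# Independent oracles: every function here recomputes a quantity by a route
# deliberately different from the package implementation (direct arithmetic,
# finite differences, grid search, full determinant enumeration, a separate
# unidimensional EM). None of them call into the package's fast paths.

# direct logistic arithmetic for GRM category probabilities
oracle_grm_prob <- function(a, d, theta) {
  z <- sum(a * theta)
  Pstar <- c(1, 1 / (1 + exp(-(z + d))), 0)
  K <- length(d) + 1L
  Pstar[1:K] - Pstar[2:(K + 1L)]
}

# expected item information as the negative expected Hessian of the item
# log-likelihood, by central finite differences over all categories
oracle_item_info_fd <- function(a, d, theta, h = 1e-4) {
  D <- length(theta)
  H <- matrix(0, D, D)
  loglik_k <- function(th, k) log(oracle_grm_prob(a, d, th)[k])
  K <- length(d) + 1L
  p0 <- oracle_grm_prob(a, d, theta)
  for (r in 1:D) for (s in 1:D) {
    acc <- 0
    for (k in 1:K) {
      er <- es <- numeric(D); er[r] <- h; es[s] <- h
      d2 <- (loglik_k(theta + er + es, k) - loglik_k(theta + er - es, k) -
               loglik_k(theta - er + es, k) + loglik_k(theta - er - es, k)) /
        (4 * h^2)
      acc <- acc + p0[k] * d2
    }
    H[r, s] <- -acc
  }
  H
}

# 1-D grid search of the MAP posterior for a pattern loading on one dimension
oracle_map_grid_1d <- function(loglik_fun, lo = -6, hi = 6, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  lp <- vapply(grid, function(t) loglik_fun(t) - t^2 / 2, numeric(1))
  grid[which.max(lp)]
}

# brute-force determinant rule: evaluate det(info + item info) for every
# candidate with base det(), no rank-1 shortcut
oracle_select_det <- function(bank, pattern, theta, candidates) {
  info <- posterior_information(bank, pattern, theta)
  dets <- vapply(candidates, function(i)
    det(info + grm_item_info(bank, i, theta)), numeric(1))
  candidates[which.max(dets)]
}

# ---- independent unidimensional graded-response EM (Bock-Aitkin) ----
# Own probability code, numerical-gradient M-step, 1-D quadrature only.

.uni_prob <- function(a, d, q) {
  Pstar <- rbind(1, t(sapply(d, function(dk) 1 / (1 + exp(-(a * q + dk))))), 0)
  K <- length(d) + 1L
  pmax(Pstar[1:K, , drop = FALSE] - Pstar[2:(K + 1L), , drop = FALSE], 1e-10)
}

oracle_unidim_grm <- function(X, K, n_quad = 21, max_cycles = 400,
                              tol = 1e-5) {
  q <- seq(-6, 6, length.out = n_quad)
  w <- dnorm(q); w <- w / sum(w)
  J <- ncol(X); n <- nrow(X)
  a <- rep(1, J)
  dl <- lapply(1:J, function(j) {
    pr <- sapply(seq_len(K[j] - 1L), function(k) mean(X[, j] >= k,
                                                      na.rm = TRUE))
    sort(qlogis(pmin(pmax(pr, 0.01), 0.99)) - seq_len(K[j] - 1L) * 1e-3,
         decreasing = TRUE)
  })
  ll_old <- -Inf
  for (cyc in 1:max_cycles) {
    L <- matrix(1, n, n_quad)
    for (j in 1:J) {
      P <- rbind(.uni_prob(a[j], dl[[j]], q), 1)
      idx <- ifelse(is.na(X[, j]), K[j] + 1L, X[, j] + 1L)
      L <- L * P[idx, , drop = FALSE]
    }
    marg <- as.numeric(L %*% w)
    ll <- sum(log(marg))
    post <- sweep(L, 2, w, "*") / marg
    for (j in 1:J) {
      Ind <- outer(X[, j], 0:(K[j] - 1L), "==") * 1
      Ind[is.na(Ind)] <- 0
      r <- crossprod(Ind, post)
      par0 <- c(a[j], dl[[j]][1],
                if (K[j] > 2) log(pmax(-diff(dl[[j]]), 1e-6)))
      nll <- function(p) {
        aa <- p[1]
        dd <- p[2]
        if (K[j] > 2) dd <- p[2] - cumsum(c(0, exp(p[3:(K[j])])))
        -sum(r * log(.uni_prob(aa, dd, q)))
      }
      opt <- optim(par0, nll, method = "L-BFGS-B",
                   lower = c(1e-3, rep(-Inf, K[j] - 1L)),
                   control = list(maxit = 40))
      p <- if (opt$value <= nll(par0)) opt$par else par0
      a[j] <- p[1]
      dl[[j]] <- if (K[j] > 2) p[2] - cumsum(c(0, exp(p[3:(K[j])]))) else p[2]
    }
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(a = a, d = dl, loglik = ll)
}
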