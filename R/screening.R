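# ---- Local dependence screening (Yen's Q3) and residual fit ----

#' Model residuals of a response matrix
#'
#' Per person and item: observed response minus the model-implied expected
#' score at the person's full-pattern MAP trait estimate. These are the
#' residuals entering Yen's Q3.
#'
#' @param responses persons x items matrix of 0-based categories (`NA`
#'   allowed).
#' @param bank a calibrated [item_bank()].
#' @return residual matrix of the same shape, `NA` where the response is
#'   missing; the MAP estimates are attached as attribute `"theta"`.
#' @export
grm_residuals <- function(responses, bank) {
  X <- as.matrix(responses)
  if (ncol(X) != n_items(bank))
    stop("response matrix and bank have different item counts")
  arr <- bank_arrays(bank)
  n <- nrow(X)
  Th <- matrix(0, n, bank$D)
  E <- matrix(NA_real_, n, ncol(X), dimnames = dimnames(X))
  for (j in seq_len(n)) {
    obs <- which(!is.na(X[j, ]))
    fit <- .map_core(arr, obs, as.integer(X[j, obs]))
    Th[j, ] <- fit$theta
    ev <- bank_eval(arr, fit$theta)
    # expected score = sum of boundary probabilities
    E[j, ] <- rowSums(ev$B[, -1L, drop = FALSE])
  }
  res <- X - E
  res[is.na(X)] <- NA_real_
  attr(res, "theta") <- Th
  res
}

#' Yen's Q3 local-dependence matrix
#'
#' Pairwise Pearson correlations of item residuals ([grm_residuals()]) over
#' persons with both items observed. Values above ~0.20 conventionally flag
#' locally dependent pairs.
#'
#' @inheritParams grm_residuals
#' @param min_pairs pairs with fewer jointly observed persons are `NA`.
#' @return symmetric items x items matrix of class `q3_matrix`; diagonal `NA`.
#' @export
q3_matrix <- function(responses, bank, min_pairs = 3L) {
  res <- grm_residuals(responses, bank)
  r <- suppressWarnings(stats::cor(res, use = "pairwise.complete.obs"))
  counts <- crossprod(!is.na(res))
  r[counts < min_pairs] <- NA_real_
  diag(r) <- NA_real_
  structure(r, class = c("q3_matrix", "matrix"))
}

#' @export
print.q3_matrix <- function(x, threshold = 0.20, ...) {
  v <- x[upper.tri(x)]
  cat(sprintf("Q3 matrix: %d items, max off-diagonal %.3f, %d pair(s) > %.2f\n",
              nrow(x), max(v, na.rm = TRUE),
              sum(v > threshold, na.rm = TRUE), threshold))
  invisible(x)
}

#' Prior-integrated scalar information of one item
#'
#' The trace of the item's Fisher information matrix integrated over the
#' standard-normal prior on the item's loaded dimensions (two-dimensional
#' quadrature for grouped items, one-dimensional otherwise). Used to decide
#' which member of a locally dependent pair to drop.
#'
#' @inheritParams grm_prob
#' @param n_quad,quad_range quadrature settings.
#' @return nonnegative scalar.
#' @export
item_information_scalar <- function(bank, item, n_quad = 21L,
                                    quad_range = c(-6, 6)) {
  i <- .item_index(bank, item)
  qd <- .quad_grid(n_quad, quad_range)
  a0 <- bank$items$a_general[i]
  ag <- bank$items$a_group[i]
  gi <- bank$items$group_index[i]
  d <- item_intercepts(bank, i)
  K <- bank$items$n_categories[i]
  winfo <- function(z) {
    Pb <- t(vapply(d, function(dk) stats::plogis(z + dk), numeric(length(z))))
    Pstar <- rbind(1, Pb, 0)
    q <- Pstar * (1 - Pstar)
    P <- pmax(Pstar[seq_len(K), , drop = FALSE] -
                Pstar[seq_len(K) + 1L, , drop = FALSE], .P_FLOOR)
    colSums((q[seq_len(K), , drop = FALSE] -
               q[seq_len(K) + 1L, , drop = FALSE])^2 / P)
  }
  if (gi == 0L) {
    w <- winfo(a0 * qd$q)
    return(sum(qd$w * w) * a0^2)
  }
  t0 <- rep(qd$q, each = n_quad); tg <- rep(qd$q, times = n_quad)
  wt <- rep(qd$w, each = n_quad) * rep(qd$w, times = n_quad)
  sum(wt * winfo(a0 * t0 + ag * tg)) * (a0^2 + ag^2)
}

#' Screen item pairs for local dependence and remove the weaker member
#'
#' Flags pairs whose Q3 exceeds `threshold` (signed by default, matching the
#' usual "residual correlation above 0.20" convention; set `absolute = TRUE`
#' to flag strong negative dependence too), then walks the flagged pairs in
#' descending Q3 order: a pair already resolved by an earlier removal is
#' skipped, otherwise the member with lower prior-integrated scalar
#' information ([item_information_scalar()]) is removed. Ties in Q3 are
#' ordered by item index; an information tie removes the later item.
#'
#' @param q3 a [q3_matrix()] (or any symmetric matrix of residual
#'   correlations).
#' @param bank the [item_bank()] the Q3 matrix was computed against.
#' @param threshold flagging cutoff.
#' @param absolute flag on `|Q3|` instead of signed Q3.
#' @return list of class `ld_screen`: `flagged` (data frame of flagged pairs
#'   with their Q3, per-item scalar information, and the removed member),
#'   `removed` (character vector of removed ids), `kept` (surviving ids).
#' @export
screen_local_dependence <- function(q3, bank, threshold = 0.20,
                                    absolute = FALSE) {
  ids <- bank$items$item_id
  stopifnot(nrow(q3) == length(ids))
  val <- if (absolute) abs(q3) else unclass(q3)
  ut <- which(upper.tri(val) & !is.na(val) & val > threshold, arr.ind = TRUE)
  info <- vapply(seq_along(ids), function(i)
    item_information_scalar(bank, i), numeric(1))
  if (nrow(ut)) {
    ord <- order(-val[ut], ut[, 1L], ut[, 2L])
    ut <- ut[ord, , drop = FALSE]
  }
  removed <- character(0)
  rows <- vector("list", nrow(ut))
  for (p in seq_len(nrow(ut))) {
    i <- ut[p, 1L]; j <- ut[p, 2L]
    drop_id <- NA_character_
    if (!(ids[i] %in% removed) && !(ids[j] %in% removed)) {
      drop_idx <- if (info[i] < info[j]) i
        else if (info[j] < info[i]) j
        else max(i, j)
      drop_id <- ids[drop_idx]
      removed <- c(removed, drop_id)
    }
    rows[[p]] <- data.frame(item_i = ids[i], item_j = ids[j],
                            q3 = unclass(q3)[i, j],
                            info_i = info[i], info_j = info[j],
                            removed = drop_id)
  }
  flagged <- if (length(rows)) do.call(rbind, rows)
    else data.frame(item_i = character(0), item_j = character(0),
                    q3 = numeric(0), info_i = numeric(0),
                    info_j = numeric(0), removed = character(0))
  structure(list(flagged = flagged, removed = removed,
                 kept = setdiff(ids, removed), threshold = threshold),
            class = "ld_screen")
}

#' @export
print.ld_screen <- function(x, ...) {
  cat(sprintf("Local-dependence screen (Q3 > %.2f): %d flagged pair(s), %d item(s) removed\n",
              x$threshold, nrow(x$flagged), length(x$removed)))
  if (length(x$removed))
    cat("  removed:", paste(x$removed, collapse = ", "), "\n")
  invisible(x)
}

#' Drop items from a bank
#'
#' @param bank an [item_bank()].
#' @param items item ids or indices to drop.
#' @return the reduced [item_bank()].
#' @export
drop_items <- function(bank, items) {
  idx <- if (is.character(items)) match(items, bank$items$item_id)
    else as.integer(items)
  if (anyNA(idx)) stop("unknown item id(s)")
  item_bank(bank$items[-idx, , drop = FALSE], G = bank$G)
}

#' Standardized root mean square residual of inter-item correlations
#'
#' Compares the observed inter-item Pearson correlation matrix with the
#' model-implied one (first and second moments of each item, and cross
#' moments of each pair, obtained by quadrature over the pair's shared
#' dimensions) and returns the root mean square of their differences over
#' all item pairs.
#'
#' @inheritParams grm_residuals
#' @param n_quad,quad_range quadrature settings.
#' @return nonnegative scalar.
#' @export
srmsr <- function(responses, bank, n_quad = 21L, quad_range = c(-6, 6)) {
  X <- as.matrix(responses)
  J <- n_items(bank)
  stopifnot(ncol(X) == J)
  qd <- .quad_grid(n_quad, quad_range)
  m1 <- n_quad
  t0 <- rep(qd$q, each = m1); tg <- rep(qd$q, times = m1)
  w2 <- rep(qd$w, each = m1) * rep(qd$w, times = m1)
  it <- bank$items
  Egrid <- matrix(0, J, m1^2)   # E(x | t0, tg) on the 2-D grid
  for (i in seq_len(J)) {
    d <- item_intercepts(bank, i)
    z <- it$a_general[i] * t0 +
      if (it$group_index[i] > 0L) it$a_group[i] * tg else 0
    for (dk in d) Egrid[i, ] <- Egrid[i, ] + stats::plogis(z + dk)
  }
  E2grid <- matrix(0, J, m1^2)  # E(x^2 | t0, tg)
  for (i in seq_len(J)) {
    d <- item_intercepts(bank, i)
    z <- it$a_general[i] * t0 +
      if (it$group_index[i] > 0L) it$a_group[i] * tg else 0
    K <- it$n_categories[i]
    P <- if (it$group_index[i] > 0L)
      .item_prob_grid(it$a_general[i], it$a_group[i], d, t0, tg)
    else .item_prob_grid(it$a_general[i], 0, d, t0, NULL)
    E2grid[i, ] <- colSums((0:(K - 1L))^2 * P)
  }
  # collapse over the group dimension: Ebar_i(t0)
  Smat <- outer(rep(seq_len(m1), each = m1), seq_len(m1), "==") * 1
  wgcol <- rep(qd$w, times = m1)
  Ebar <- sweep(Egrid, 2L, wgcol, "*") %*% Smat     # J x m1
  mu <- as.numeric(Egrid %*% w2)
  ex2 <- as.numeric(E2grid %*% w2)
  sdv <- sqrt(pmax(ex2 - mu^2, 1e-12))
  r_obs <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  diffs <- c()
  for (i in seq_len(J - 1L)) for (j in (i + 1L):J) {
    if (is.na(r_obs[i, j])) next
    exy <- if (it$group_index[i] > 0L && it$group_index[i] == it$group_index[j])
      sum(w2 * Egrid[i, ] * Egrid[j, ])
    else
      sum(qd$w * Ebar[i, ] * Ebar[j, ])
    r_mod <- (exy - mu[i] * mu[j]) / (sdv[i] * sdv[j])
    diffs <- c(diffs, r_obs[i, j] - r_mod)
  }
  sqrt(mean(diffs^2))
}
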