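# probability floor used inside logarithms; prevents -Inf at extreme theta
.P_FLOOR <- 1e-10

# Flat arrays for vectorized evaluation of a whole bank at one theta.
# dmat is n_items x (maxK - 1) with NA beyond each item's K_i - 1.
bank_arrays <- function(bank) {
  it <- bank$items
  maxK <- max(it$n_categories)
  dmat <- as.matrix(it[, paste0("d", seq_len(maxK - 1L)), drop = FALSE])
  storage.mode(dmat) <- "double"
  Btmpl <- matrix(0, nrow(it), maxK + 1L)
  Btmpl[, 1L] <- 1
  list(a0 = it$a_general, ag = it$a_group, gi = it$group_index,
       K = it$n_categories, dmat = dmat, maxK = maxK,
       namask = is.na(dmat), Btmpl = Btmpl,
       D = bank$D, n = nrow(it), ids = it$item_id)
}

# Boundary/category machinery for every item at a single theta.
# Returns B (n x maxK+1 boundary probs, col 1 = 1, trailing cols 0),
# P (n x maxK category probs, 0 beyond K_i), q = B(1-B), z (linear predictor).
bank_eval <- function(arr, theta) {
  z <- arr$a0 * theta[1L] +
    arr$ag * ifelse(arr$gi > 0L, theta[arr$gi + 1L], 0)
  Pstar <- stats::plogis(z + arr$dmat)
  Pstar[is.na(Pstar)] <- 0
  B <- cbind(1, Pstar, 0, deparse.level = 0)
  m <- arr$maxK
  P <- B[, 1:m, drop = FALSE] - B[, 2:(m + 1L), drop = FALSE]
  list(B = B, P = P, q = B * (1 - B), z = z)
}

# scalar Fisher-information weight w(z) for every item at one theta:
# w = sum_k (q_k - q_{k+1})^2 / P_k with q_k = P*_k (1 - P*_k)
bank_info_weights <- function(arr, theta, ev = bank_eval(arr, theta)) {
  m <- arr$maxK
  num <- (ev$q[, 1:m, drop = FALSE] - ev$q[, 2:(m + 1L), drop = FALSE])^2
  ok <- ev$P > 0
  w <- numeric(arr$n)
  contrib <- num
  contrib[ok] <- contrib[ok] / ev$P[ok]
  contrib[!ok] <- 0
  rowSums(contrib)
}

.check_theta <- function(bank, theta) {
  if (length(theta) != bank$D)
    stop(sprintf("theta must have length D = %d, got %d", bank$D,
                 length(theta)))
  if (any(!is.finite(theta))) stop("theta entries must be finite")
  invisible(theta)
}

.item_index <- function(bank, item) {
  if (is.character(item)) {
    i <- match(item, bank$items$item_id)
    if (is.na(i)) stop("unknown item_id: ", item)
    return(i)
  }
  i <- as.integer(item)
  if (i < 1L || i > nrow(bank$items)) stop("item index out of range")
  i
}

#' Category probabilities of one item under the bifactor GRM
#'
#' The graded response model assigns boundary probabilities
#' `P*_k = plogis(a_general theta_1 + a_group theta_g + d_k)` for
#' `k = 1..K-1` (with `P*_0 = 1`, `P*_K = 0`) and category probabilities
#' `P_k = P*_k - P*_{k+1}`. Categories are 0-based (`0..K-1`).
#'
#' @param bank an [item_bank()].
#' @param item item index or `item_id`.
#' @param theta numeric latent-trait vector of length `D` (general factor
#'   first, then group factors), in trait-SD units.
#' @return numeric vector of `K` probabilities summing to 1.
#' @export
grm_prob <- function(bank, item, theta) {
  .check_theta(bank, theta)
  i <- .item_index(bank, item)
  K <- bank$items$n_categories[i]
  a <- item_loadings(bank, i)
  z <- sum(a * theta)
  Pstar <- c(1, stats::plogis(z + item_intercepts(bank, i)), 0)
  Pstar[seq_len(K)] - Pstar[seq_len(K) + 1L]
}

#' Expected Fisher information of one item
#'
#' Returns the `D x D` expected information matrix `w(z) a a'` where `a` is
#' the item's sparse loading vector; it is rank <= 1 and supported only on
#' the general dimension and the item's group dimension.
#'
#' @inheritParams grm_prob
#' @return `D x D` positive semidefinite matrix.
#' @export
grm_item_info <- function(bank, item, theta) {
  .check_theta(bank, theta)
  i <- .item_index(bank, item)
  a <- item_loadings(bank, i)
  z <- sum(a * theta)
  q <- c(0, {p <- stats::plogis(z + item_intercepts(bank, i)); p * (1 - p)}, 0)
  Pstar <- c(1, stats::plogis(z + item_intercepts(bank, i)), 0)
  K <- bank$items$n_categories[i]
  P <- Pstar[seq_len(K)] - Pstar[seq_len(K) + 1L]
  w <- sum((q[seq_len(K)] - q[seq_len(K) + 1L])^2 / pmax(P, .P_FLOOR))
  w * tcrossprod(a)
}

#' Log-likelihood of a (possibly partial) response pattern
#'
#' Missing responses (`NA`) contribute nothing to the sum (full-information
#' treatment of missingness). Responses are 0-based category codes.
#'
#' @inheritParams grm_prob
#' @param pattern integer vector of length `n_items(bank)`; entries in
#'   `0..K_i - 1` or `NA`.
#' @return scalar log-likelihood.
#' @export
grm_loglik <- function(bank, pattern, theta) {
  .check_theta(bank, theta)
  if (length(pattern) != n_items(bank))
    stop("pattern length must equal the number of bank items")
  obs <- which(!is.na(pattern))
  K <- bank$items$n_categories
  if (any(pattern[obs] < 0L | pattern[obs] >= K[obs]))
    stop("response outside 0..K-1 for its item")
  if (!length(obs)) return(0)
  arr <- bank_arrays(bank)
  ev <- bank_eval(arr, theta)
  p <- ev$P[cbind(obs, pattern[obs] + 1L)]
  sum(log(pmax(p, .P_FLOOR)))
}

#' Model-implied expected score of one item
#'
#' `E(x) = sum_k k P_k(theta)` over 0-based categories; equals the sum of the
#' boundary probabilities. Used for Yen's Q3 residuals.
#'
#' @inheritParams grm_prob
#' @return scalar in `[0, K - 1]`.
#' @export
grm_expected_score <- function(bank, item, theta) {
  p <- grm_prob(bank, item, theta)
  sum((seq_along(p) - 1) * p)
}

#' Convert between difficulty-style and intercept-style thresholds
#'
#' Some parameter tables report per-boundary difficulties `b_k` (increasing)
#' instead of intercepts `d_k` (decreasing). The conversion used here is
#' `d_k = -b_k * ||a||` with `||a||` the Euclidean norm of the item's loading
#' vector, matching the common multidimensional-IRT convention.
#'
#' @param a_general,a_group item slopes.
#' @param difficulties strictly increasing numeric vector of `K - 1`
#'   difficulties.
#' @return numeric vector of strictly decreasing intercepts.
#' @export
intercepts_from_difficulties <- function(a_general, a_group, difficulties) {
  if (length(difficulties) > 1L && any(diff(difficulties) <= 0))
    stop("difficulties must be strictly increasing")
  -difficulties * sqrt(a_general^2 + a_group^2)
}

#' @rdname intercepts_from_difficulties
#' @param intercepts strictly decreasing numeric vector of intercepts.
#' @export
difficulties_from_intercepts <- function(a_general, a_group, intercepts) {
  if (length(intercepts) > 1L && any(diff(intercepts) >= 0))
    stop("intercepts must be strictly decreasing")
  -intercepts / sqrt(a_general^2 + a_group^2)
}
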