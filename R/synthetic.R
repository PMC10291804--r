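# ---- Synthetic study inputs: latent traits, item banks, GRM responses ----

# run expr under a private RNG stream, leaving the caller's stream untouched
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Specification of a synthetic bifactor item bank
#'
#' The defaults emulate a 44-item health-related-quality-of-life bank with
#' one general factor and ten group factors (41 items split across the group
#' factors plus three general-only items), mixed 2/3/5/6-point response
#' formats, general-factor slopes in `[0.92, 4.71]`, group slopes in
#' `[0.56, 5.19]`, and boundary difficulties spread over `[-2.5, 2.5]` on the
#' latent continuum (converted to intercepts with the item's loading norm).
#'
#' @param G number of group factors.
#' @param items_per_factor named integer vector, items per group factor.
#' @param n_general_only items loading on the general factor only.
#' @param categories_per_factor integer vector of length `G`, response
#'   categories for items of each group factor.
#' @param categories_general_only categories for general-only items.
#' @param a_general_range,a_group_range uniform slope ranges (logit units).
#' @param difficulty_range range of boundary difficulties (trait-SD units).
#' @param seed default seed used by [generate_item_bank()].
#' @return a list of class `bank_spec`.
#' @export
bank_spec <- function(G = 10L,
                      items_per_factor = c(physical_function = 6L,
                                           role_physical = 4L,
                                           role_emotional = 3L,
                                           pain = 3L,
                                           emotional_wellbeing = 5L,
                                           energy = 4L,
                                           health_perceptions = 5L,
                                           cognitive = 3L,
                                           health_distress = 4L,
                                           sexual_function = 4L),
                      n_general_only = 3L,
                      categories_per_factor = c(3L, 2L, 2L, 6L, 6L, 6L,
                                                5L, 6L, 5L, 5L),
                      categories_general_only = 5L,
                      a_general_range = c(0.92, 4.71),
                      a_group_range = c(0.56, 5.19),
                      difficulty_range = c(-2.5, 2.5),
                      seed = 1L) {
  stopifnot(length(items_per_factor) == G,
            length(categories_per_factor) == G,
            all(items_per_factor >= 1L),
            all(categories_per_factor >= 2L),
            categories_general_only >= 2L,
            diff(a_general_range) >= 0, a_general_range[1] > 0,
            diff(a_group_range) >= 0,
            diff(difficulty_range) > 0)
  structure(list(G = as.integer(G),
                 items_per_factor = as.integer(items_per_factor),
                 n_general_only = as.integer(n_general_only),
                 categories_per_factor = as.integer(categories_per_factor),
                 categories_general_only = as.integer(categories_general_only),
                 a_general_range = a_general_range,
                 a_group_range = a_group_range,
                 difficulty_range = difficulty_range,
                 seed = seed),
            class = "bank_spec")
}

#' Generate true latent traits
#'
#' Draws `n` respondents from MVN(0, I_D): independent standard normals on
#' every dimension (general factor first), matching the bifactor convention
#' of mutually uncorrelated factors.
#'
#' @param n number of respondents.
#' @param D number of dimensions (`G + 1`).
#' @param seed integer seed; the draw uses a private RNG stream.
#' @return `n x D` numeric matrix.
#' @export
generate_thetas <- function(n, D, seed = NULL) {
  stopifnot(n >= 1, D >= 1)
  .with_seed(seed, matrix(stats::rnorm(n * D), nrow = n, ncol = D))
}

#' Generate a synthetic bifactor item bank
#'
#' Slopes are drawn uniformly within the spec's ranges; boundary difficulties
#' are sorted uniforms on the difficulty range (minimum gap 0.1 to keep
#' adjacent boundaries distinct) converted to intercepts via
#' [intercepts_from_difficulties()].
#'
#' @param spec a [bank_spec()].
#' @param seed integer seed; defaults to `spec$seed`.
#' @return an [item_bank()].
#' @export
generate_item_bank <- function(spec = bank_spec(), seed = spec$seed) {
  .with_seed(seed, {
    gi <- c(rep(seq_len(spec$G), spec$items_per_factor),
            rep(0L, spec$n_general_only))
    K <- c(rep(spec$categories_per_factor, spec$items_per_factor),
           rep(spec$categories_general_only, spec$n_general_only))
    n <- length(gi)
    a0 <- stats::runif(n, spec$a_general_range[1], spec$a_general_range[2])
    ag <- ifelse(gi > 0L,
                 stats::runif(n, spec$a_group_range[1], spec$a_group_range[2]),
                 0)
    maxK <- max(K)
    dmat <- matrix(NA_real_, n, maxK - 1L)
    for (i in seq_len(n)) {
      repeat {
        b <- sort(stats::runif(K[i] - 1L, spec$difficulty_range[1],
                               spec$difficulty_range[2]))
        if (K[i] == 2L || min(diff(b)) >= 0.1) break
      }
      dmat[i, seq_len(K[i] - 1L)] <- intercepts_from_difficulties(a0[i],
                                                                  ag[i], b)
    }
    df <- data.frame(item_id = sprintf("item%02d", seq_len(n)),
                     group_index = gi, n_categories = K,
                     a_general = a0, a_group = ag)
    for (k in seq_len(maxK - 1L)) df[[paste0("d", k)]] <- dmat[, k]
    item_bank(df, G = spec$G)
  })
}

#' Simulate GRM responses for given true traits
#'
#' For each person and item the response category is drawn from the bifactor
#' GRM category probabilities at the person's true trait vector, using the
#' inverse-boundary construction (one uniform per response).
#'
#' @param thetas `n x D` matrix of true traits.
#' @param bank an [item_bank()].
#' @param seed integer seed; the draw uses a private RNG stream.
#' @param missing_rate optional proportion of entries set missing completely
#'   at random (default 0: complete data).
#' @return `n x n_items` integer matrix of 0-based categories, with `NA` for
#'   missing entries; columns named by `item_id`.
#' @export
simulate_responses <- function(thetas, bank, seed = NULL, missing_rate = 0) {
  thetas <- as.matrix(thetas)
  if (ncol(thetas) != bank$D)
    stop(sprintf("thetas must have D = %d columns", bank$D))
  stopifnot(missing_rate >= 0, missing_rate < 1)
  .with_seed(seed, {
    n <- nrow(thetas)
    it <- bank$items
    X <- matrix(0L, n, nrow(it), dimnames = list(NULL, it$item_id))
    for (i in seq_len(nrow(it))) {
      g <- it$group_index[i]
      z <- it$a_general[i] * thetas[, 1L] +
        if (g > 0L) it$a_group[i] * thetas[, g + 1L] else 0
      u <- stats::runif(n)
      x <- integer(n)
      for (d in item_intercepts(bank, i))
        x <- x + (u <= stats::plogis(z + d))
      X[, i] <- x
    }
    if (missing_rate > 0) {
      drop <- stats::runif(length(X)) < missing_rate
      X[drop] <- NA_integer_
    }
    X
  })
}
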