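#' Construct an item bank for the bifactor graded response model
#'
#' An item bank holds the calibrated parameters of a set of polytomous items
#' under a bifactor structure: every item discriminates on the general factor
#' (dimension 1) and on at most one of `G` group factors (dimensions
#' `2..G+1`). Items are parameterized in slope--intercept form with a logistic
#' link: the boundary ("cumulative") probability of scoring in category `k` or
#' above is `plogis(a_general * theta_1 + a_group * theta_g + d_k)`, with the
#' intercepts `d_1 > d_2 > ... > d_{K-1}` strictly decreasing so that all
#' category probabilities are nonnegative.
#'
#' @param items a `data.frame` with one row per item and columns `item_id`
#'   (unique labels), `group_index` (integer in `0..G`; 0 means the item loads
#'   on the general factor only), `n_categories` (integer `K >= 2`),
#'   `a_general` (positive slope on the general factor, logit units per trait
#'   SD), `a_group` (slope on the item's group factor; must be 0 when
#'   `group_index` is 0), and `d1`, `d2`, ... holding the `K - 1` intercepts
#'   (cells beyond `K - 1` must be `NA`).
#' @param G number of group factors. Defaults to `max(group_index)`.
#'
#' @return an object of class `item_bank`: a list with elements `items` (the
#'   validated parameter table), `G`, and `D = G + 1` (total dimensions,
#'   general factor first).
#' @seealso [generate_item_bank()], [read_item_bank()], [bfgrm()]
#' @export
item_bank <- function(items, G = NULL) {
  stopifnot(is.data.frame(items))
  req <- c("item_id", "group_index", "n_categories", "a_general", "a_group")
  miss <- setdiff(req, names(items))
  if (length(miss))
    stop("item table lacks columns: ", paste(miss, collapse = ", "))
  items$item_id <- as.character(items$item_id)
  items$group_index <- as.integer(items$group_index)
  items$n_categories <- as.integer(items$n_categories)
  if (is.null(G)) G <- max(items$group_index, 0L)
  G <- as.integer(G)
  maxK <- max(items$n_categories)
  dcols <- paste0("d", seq_len(maxK - 1L))
  for (dc in dcols) if (!dc %in% names(items)) items[[dc]] <- NA_real_
  items <- items[, c(req, paste0("d", seq_len(max(items$n_categories) - 1L)))]
  bank <- structure(list(items = items, G = G, D = G + 1L),
                    class = "item_bank")
  validate_item_bank(bank)
  bank
}

#' @rdname item_bank
#' @param bank an `item_bank` object.
#' @export
validate_item_bank <- function(bank) {
  it <- bank$items
  if (anyDuplicated(it$item_id))
    stop("duplicated item_id: ",
         paste(unique(it$item_id[duplicated(it$item_id)]), collapse = ", "))
  if (any(it$n_categories < 2L))
    stop("n_categories must be >= 2")
  if (any(it$group_index < 0L | it$group_index > bank$G))
    stop("group_index outside 0..G")
  if (any(!is.finite(it$a_general)) || any(it$a_general <= 0))
    stop("a_general must be finite and positive")
  if (any(it$group_index == 0L & it$a_group != 0))
    stop("general-only items (group_index 0) must have a_group = 0")
  for (i in seq_len(nrow(it))) {
    d <- item_intercepts(bank, i)
    if (any(!is.finite(d)))
      stop("item ", it$item_id[i], ": missing or non-finite intercepts")
    if (it$n_categories[i] > 2L && any(diff(d) >= 0))
      stop("item ", it$item_id[i], ": intercepts must be strictly decreasing")
    extra <- unlist(it[i, paste0("d", seq_len(ncol(it) - 5L))])[-seq_len(it$n_categories[i] - 1L)]
    if (length(extra) && any(!is.na(extra)))
      stop("item ", it$item_id[i], ": intercept cells beyond K-1 must be empty")
  }
  invisible(bank)
}

# intercepts of item i (length K_i - 1)
item_intercepts <- function(bank, i) {
  K <- bank$items$n_categories[i]
  as.numeric(bank$items[i, paste0("d", seq_len(K - 1L)), drop = TRUE])
}

# D-length sparse loading vector of item i
item_loadings <- function(bank, i) {
  a <- numeric(bank$D)
  a[1L] <- bank$items$a_general[i]
  g <- bank$items$group_index[i]
  if (g > 0L) a[g + 1L] <- bank$items$a_group[i]
  a
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("Bifactor item bank: %d items, %d group factor(s), D = %d\n",
              nrow(x$items), x$G, x$D))
  cat(sprintf("  categories %d-%d; a_general in [%.2f, %.2f]",
              min(x$items$n_categories), max(x$items$n_categories),
              min(x$items$a_general), max(x$items$a_general)))
  grp <- x$items$a_group[x$items$group_index > 0L]
  if (length(grp))
    cat(sprintf("; a_group in [%.2f, %.2f]", min(grp), max(grp)))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.item_bank <- function(x, ...) x$items

#' Number of items in a bank
#' @param bank an `item_bank`.
#' @return integer item count.
#' @export
n_items <- function(bank) nrow(bank$items)
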