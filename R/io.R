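# ---- File formats: item banks, response matrices, designs, summaries ----
#
# All delimited files are comma-separated UTF-8 with "." decimals and empty
# cells for missing values; numbers are written with 12 significant digits
# so write -> read round-trips are bit-stable.

.fmt_num <- function(x) ifelse(is.na(x), "", formatC(x, digits = 12,
                                                     format = "g"))

#' Read / write an item bank
#'
#' The delimited dialect has one row per item with columns `item_id`,
#' `group_index` (0 = general-only), `n_categories`, `a_general`, `a_group`,
#' and `d1..d{maxK-1}` (cells beyond an item's `K - 1` empty). With
#' `dialect = "difficulty"` the `d*` columns are read as increasing
#' difficulties and converted via [intercepts_from_difficulties()]. A JSON
#' serialization of the same content is used for `.json` paths.
#'
#' @param path file path (`.csv` or `.json`).
#' @param dialect `"intercept"` (native) or `"difficulty"`.
#' @param G number of group factors; defaults to the largest `group_index`.
#' @return an [item_bank()].
#' @export
read_item_bank <- function(path, dialect = c("intercept", "difficulty"),
                           G = NULL) {
  dialect <- match.arg(dialect)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(path)
    as.data.frame(obj$items)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  req <- c("item_id", "group_index", "n_categories", "a_general", "a_group")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("bank file lacks columns: ", paste(miss, collapse = ", "))
  dcols <- grep("^d[0-9]+$", names(df), value = TRUE)
  if (dialect == "difficulty") {
    for (i in seq_len(nrow(df))) {
      K <- df$n_categories[i]
      b <- as.numeric(df[i, paste0("d", seq_len(K - 1L))])
      d <- tryCatch(
        intercepts_from_difficulties(df$a_general[i], df$a_group[i], b),
        error = function(e) stop("row ", i, " (", df$item_id[i], "): ",
                                 conditionMessage(e)))
      df[i, paste0("d", seq_len(K - 1L))] <- d
    }
  }
  tryCatch(item_bank(df, G = G),
           error = function(e) stop("invalid bank file ", path, ": ",
                                    conditionMessage(e)))
}

#' @rdname read_item_bank
#' @param bank an [item_bank()].
#' @export
write_item_bank <- function(bank, path) {
  df <- bank$items
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(G = bank$G, items = df), path,
                         auto_unbox = TRUE, digits = NA, na = "null")
    return(invisible(path))
  }
  out <- df
  for (nm in names(out))
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]]))
      out[[nm]] <- .fmt_num(out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read / write a response matrix
#'
#' Delimited text with a header row of item ids, one row per person, empty
#' cells for missing responses. When a bank is supplied the header must be
#' a subset of its items (warning when a proper subset) and every value is
#' validated against the item's category range; violations are reported
#' with their coordinates.
#'
#' @param path file path.
#' @param bank optional [item_bank()] to validate against.
#' @return integer matrix with `NA` for missing entries.
#' @export
read_response_matrix <- function(path, bank = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  X <- as.matrix(df)
  storage.mode(X) <- "integer"
  if (!is.null(bank)) {
    unknown <- setdiff(colnames(X), bank$items$item_id)
    if (length(unknown))
      stop("response columns not in bank: ", paste(unknown, collapse = ", "))
    if (ncol(X) < n_items(bank))
      warning("response matrix covers a subset of the bank's items")
    K <- bank$items$n_categories[match(colnames(X), bank$items$item_id)]
    for (j in seq_len(ncol(X))) {
      bad <- which(X[, j] < 0L | X[, j] >= K[j])
      if (length(bad))
        stop(sprintf("out-of-range response at row %d, item %s (value %d)",
                     bad[1L], colnames(X)[j], X[bad[1L], j]))
    }
  }
  X
}

#' @rdname read_response_matrix
#' @param responses integer response matrix.
#' @export
write_response_matrix <- function(responses, path) {
  utils::write.csv(as.data.frame(responses), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Read / write a stopping-rule design
#'
#' Structured text (YAML or JSON by extension): a list of blocks with
#' `name` and optional `se_general`, `se_group`, `theta_change`,
#' `max_items`. [write_design()] serializes a design; the bundled
#' [table3_design()] is the package default.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return a `simulation_design` (named list of [termination_policy()]).
#' @export
read_design <- function(path) {
  rows <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  design <- lapply(rows, function(r)
    termination_policy(se_general = r$se_general, se_group = r$se_group,
                       theta_change = r$theta_change,
                       max_items = r$max_items, name = r$name))
  names(design) <- vapply(rows, function(r)
    if (is.null(r$name)) "" else r$name, character(1))
  if (any(names(design) == "") || anyDuplicated(names(design)))
    stop("design rows need unique names")
  structure(design, class = "simulation_design")
}

#' @rdname read_design
#' @param design a `simulation_design`.
#' @export
write_design <- function(design, path) {
  rows <- lapply(design, function(p)
    Filter(Negate(is.null),
           list(name = p$name, se_general = p$se_general,
                se_group = p$se_group, theta_change = p$theta_change,
                max_items = p$max_items)))
  names(rows) <- NULL
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(rows, path)
  else jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}

#' Write administration records as delimited text
#'
#' One row per respondent per design row: design name, respondent index,
#' item count, stop reason, final general-factor estimate and SE, and the
#' administered item sequence (semicolon-separated).
#'
#' @param runs an `mcat_runs` object.
#' @param path output CSV path.
#' @export
write_records <- function(runs, path) {
  rows <- list()
  for (nm in names(runs$records)) {
    recs <- runs$records[[nm]]
    rows[[nm]] <- data.frame(
      design = nm,
      respondent = seq_along(recs),
      n_items = vapply(recs, `[[`, numeric(1), "n_items"),
      stop_reason = vapply(recs, `[[`, character(1), "stop_reason"),
      theta_general = vapply(recs, function(r) r$theta[1L], numeric(1)),
      se_general = vapply(recs, function(r) r$se[1L], numeric(1)),
      items = vapply(recs, function(r) paste(r$items, collapse = ";"),
                     character(1)))
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
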