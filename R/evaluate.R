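# ---- Performance metrics: RMSD, correlation, item reduction, summaries ----

#' Root mean square difference between estimated and true traits
#'
#' `sqrt(sum((est - truth)^2) / N)`; lower is more accurate.
#'
#' @param estimates,truths numeric vectors of equal length.
#' @return nonnegative scalar.
#' @export
rmsd <- function(estimates, truths) {
  if (length(estimates) != length(truths)) stop("length mismatch")
  if (!length(estimates)) stop("need at least one pair")
  sqrt(mean((estimates - truths)^2))
}

#' Pearson correlation between estimated and true traits
#'
#' Thin wrapper around [stats::cor()] with input checks (length >= 3 and
#' nonzero variance on both sides).
#'
#' @inheritParams rmsd
#' @return correlation in `[-1, 1]`.
#' @export
pearson_correlation <- function(estimates, truths) {
  if (length(estimates) != length(truths)) stop("length mismatch")
  if (length(estimates) < 3L) stop("need at least 3 pairs")
  if (stats::sd(estimates) == 0 || stats::sd(truths) == 0)
    stop("zero-variance input")
  stats::cor(estimates, truths)
}

#' Item reduction relative to the full-length instrument
#'
#' `100 (1 - mean_items / bank_size)`, the percentage of the instrument
#' saved by adaptive administration.
#'
#' @param mean_items mean number of administered items.
#' @param bank_size full bank size.
#' @return percentage in `[0, 100)`.
#' @export
item_reduction <- function(mean_items, bank_size) {
  if (mean_items <= 0 || mean_items > bank_size)
    stop("mean_items must be in (0, bank_size]")
  100 * (1 - mean_items / bank_size)
}

#' Reliability implied by a standard-error threshold
#'
#' The classical conversion `reliability = 1 - SE^2` linking a stopping
#' precision to marginal reliability (e.g. SE 0.50 -> 0.75, SE 0.32 -> 0.90
#' after rounding).
#'
#' @param se standard error in `[0, 1]`.
#' @return reliability in `[0, 1]`.
#' @export
se_to_reliability <- function(se) {
  if (any(se < 0 | se > 1)) stop("the conversion assumes SE in [0, 1]")
  1 - se^2
}

#' Summarize MCAT runs against the true traits
#'
#' Produces the per-design-row performance table: administered-item counts
#' (mean, median, IQR as the interpolated 25th-75th percentiles), item
#' reduction from the mean, the general-factor SE at termination (mean and
#' range), and per-dimension correlation and RMSD of the final trait
#' estimates against the truths, plus their across-group-factor means.
#'
#' @param runs an `mcat_runs` object from [run_design()].
#' @param truths the `n x D` true trait matrix the responses were simulated
#'   from.
#' @param reference optional design-row name to difference against (e.g.
#'   `"full"`): adds columns for the loss in general-factor correlation and
#'   RMSD relative to that row.
#' @return a `data.frame` with one row per design row; per-dimension
#'   correlations and RMSDs are attached as attribute `"by_dimension"`.
#' @export
summarize_simulation <- function(runs, truths, reference = NULL) {
  truths <- as.matrix(truths)
  D <- runs$D
  stopifnot(ncol(truths) == D)
  bank_size <- length(runs$item_ids)
  rows <- list(); bydim <- list()
  for (nm in names(runs$records)) {
    recs <- runs$records[[nm]]
    stopifnot(length(recs) == nrow(truths))
    ni <- vapply(recs, `[[`, numeric(1), "n_items")
    Th <- t(vapply(recs, `[[`, numeric(D), "theta"))
    Se <- t(vapply(recs, `[[`, numeric(D), "se"))
    # a dimension no administered item ever loaded on has all estimates at
    # the prior mode; its correlation is undefined, not an error
    cors <- vapply(seq_len(D), function(d)
      if (stats::sd(Th[, d]) == 0) NA_real_
      else pearson_correlation(Th[, d], truths[, d]), numeric(1))
    rmsds <- vapply(seq_len(D), function(d)
      rmsd(Th[, d], truths[, d]), numeric(1))
    qs <- stats::quantile(ni, c(0.25, 0.75), type = 7)
    rows[[nm]] <- data.frame(
      design = nm,
      mean_items = mean(ni), median_items = stats::median(ni),
      items_q25 = qs[[1L]], items_q75 = qs[[2L]],
      item_reduction = item_reduction(mean(ni), bank_size),
      se_general_mean = mean(Se[, 1L]),
      se_general_min = min(Se[, 1L]), se_general_max = max(Se[, 1L]),
      cor_general = cors[1L], rmsd_general = rmsds[1L],
      cor_group_mean = if (D > 1L) mean(cors[-1L], na.rm = TRUE)
        else NA_real_,
      rmsd_group_mean = if (D > 1L) mean(rmsds[-1L]) else NA_real_,
      se_group_mean = if (D > 1L) mean(Se[, -1L]) else NA_real_)
    bydim[[nm]] <- data.frame(design = nm, dimension = seq_len(D) - 1L,
                              cor = cors, rmsd = rmsds,
                              se_mean = colMeans(Se))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(reference)) {
    if (!reference %in% out$design) stop("unknown reference row")
    ref <- out[out$design == reference, ]
    out$cor_general_loss <- ref$cor_general - out$cor_general
    out$rmsd_general_gain <- out$rmsd_general - ref$rmsd_general
  }
  attr(out, "by_dimension") <- do.call(rbind, bydim)
  out
}
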