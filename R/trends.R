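# Tabular change statistics: per-interval area decrements and rates,
# driver correlations (Pearson, two-tailed), and confusion-matrix
# accuracy / kappa.

#' Area time series
#'
#' @param year Strictly increasing integer years.
#' @param total_area_km2,farmland_area_km2 Positive areas; farmland must
#'   not exceed the total.
#' @return data.frame of class `area_time_series`.
#' @export
area_time_series <- function(year, total_area_km2, farmland_area_km2) {
  stopifnot(length(year) == length(total_area_km2),
            length(year) == length(farmland_area_km2))
  if (anyDuplicated(year)) stop("duplicate years")
  if (is.unsorted(year, strictly = TRUE)) stop("years must be increasing")
  if (any(total_area_km2 <= 0) || any(farmland_area_km2 <= 0)) {
    stop("areas must be positive")
  }
  if (any(farmland_area_km2 > total_area_km2)) {
    stop("farmland area exceeds total area")
  }
  structure(
    data.frame(year = as.integer(year), total_area_km2 = total_area_km2,
               farmland_area_km2 = farmland_area_km2),
    class = c("area_time_series", "data.frame")
  )
}

#' Read an area time series from CSV
#'
#' Expects columns `year`, `total_area_km2`, `farmland_area_km2`.
#' @param path CSV path.
#' @return An [area_time_series()].
#' @export
read_area_series <- function(path) {
  df <- utils::read.csv(path)
  area_time_series(df$year, df$total_area_km2, df$farmland_area_km2)
}

#' Per-interval change statistics
#'
#' For each pair of consecutive dates: the average annual change
#' `(area2 - area1) / (year2 - year1)` in km2/yr, the average annual
#' change rate relative to the interval-start area in %/yr, and the
#' per-year farmland proportion in %. Losses come out negative. Values are
#' full precision; `rounded = TRUE` applies the 2-decimal report rounding.
#'
#' @param ts An [area_time_series()] with at least 2 rows.
#' @param rounded Round to 2 decimals at the reporting boundary.
#' @return data.frame with columns `year`, `proportion_pct`,
#'   `annual_decrement_km2`, `annual_decrement_rate_pct` (the latter two
#'   `NA` for the first year).
#' @export
change_statistics <- function(ts, rounded = FALSE) {
  stopifnot(inherits(ts, "area_time_series"))
  if (nrow(ts) < 2L) stop("need at least 2 rows")
  dt <- diff(ts$year)
  dec <- diff(ts$farmland_area_km2) / dt
  rate <- dec / utils::head(ts$farmland_area_km2, -1) * 100
  prop <- ts$farmland_area_km2 / ts$total_area_km2 * 100
  out <- data.frame(
    year = ts$year,
    proportion_pct = prop,
    annual_decrement_km2 = c(NA, dec),
    annual_decrement_rate_pct = c(NA, rate)
  )
  if (rounded) {
    out[-1] <- lapply(out[-1], round_report)
  }
  out
}

#' Pairwise Pearson correlations with two-tailed tests
#'
#' Standard bivariate Pearson correlation between every factor column and
#' every response column, with two-tailed p-values from the t-distribution
#' on n - 2 degrees of freedom and significance flags at 0.05 (`*`) and
#' 0.01 (`**`). Zero-variance pairs are reported as `NA` (undefined), not
#' 0.
#'
#' @param factors data.frame of per-year driver variables.
#' @param responses data.frame of per-year responses (class areas,
#'   indices), same row order.
#' @param mask_nonsignificant Blank out non-significant correlations in
#'   the `r` matrix (as published driver tables often do).
#' @return List of matrices `r`, `p`, `n`, and character matrix `flag`.
#' @export
pearson_matrix <- function(factors, responses, mask_nonsignificant = FALSE) {
  stopifnot(nrow(factors) == nrow(responses))
  fn <- names(factors); rn <- names(responses)
  r <- p <- n <- matrix(NA_real_, length(fn), length(rn),
                        dimnames = list(fn, rn))
  flag <- matrix("", length(fn), length(rn), dimnames = list(fn, rn))
  for (i in seq_along(fn)) for (j in seq_along(rn)) {
    x <- factors[[i]]; y <- responses[[j]]
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    n[i, j] <- length(x)
    if (length(x) < 3L) next
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next  # undefined, stays NA
    ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
    r[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
    flag[i, j] <- if (ct$p.value < 0.01) "**" else
      if (ct$p.value < 0.05) "*" else ""
  }
  if (mask_nonsignificant) r[flag == ""] <- NA_real_
  list(r = r, p = p, n = n, flag = flag)
}

#' Classification accuracy and kappa from a confusion matrix
#'
#' Total accuracy is the diagonal fraction `p_o = trace / total`; kappa is
#' the chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with
#' `p_e = sum(row_i * col_i) / total^2`.
#'
#' @param cm Square non-negative count matrix, rows = reference,
#'   columns = predicted.
#' @return List with `accuracy` and `kappa`.
#' @export
accuracy_kappa <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm), all(cm >= 0))
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix")
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (abs(1 - pe) < 1e-12) stop("degenerate matrix: chance agreement is 1, kappa undefined")
  list(accuracy = po, kappa = (po - pe) / (1 - pe))
}
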