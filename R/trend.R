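#' Select an ARMA error order for a metric-vs-year series
#'
#' Fits the ordinary least squares trend, places its residuals on an annual
#' lattice (missing years as `NA`, so lag semantics survive 1-4 year gaps in
#' the mapping record), and grid-searches ARMA(p, q) orders with
#' `p, q <= max_order` by maximum likelihood, minimizing the small-sample
#' corrected information criterion AICc.  Ties prefer the smaller `p + q`,
#' then the smaller `p`.  Series with fewer than `min_n` observations get
#' order (0, 0) by rule.
#'
#' @param values metric values.
#' @param years strictly increasing integer years (gaps allowed).
#' @param max_order maximum AR and MA order searched (default 2).
#' @param min_n minimum observations for a non-trivial order (default 8).
#' @return integer vector `c(p, q)`.
#' @export
select_error_structure <- function(values, years, max_order = 2, min_n = 8) {
  ok <- !is.na(values) & !is.na(years)
  values <- values[ok]; years <- as.integer(years[ok])
  if (any(diff(years) <= 0)) stop("years must be strictly increasing")
  n <- length(values)
  if (n < min_n) return(c(p = 0L, q = 0L))
  res <- stats::residuals(lm(values ~ years))
  lattice <- rep(NA_real_, max(years) - min(years) + 1L)
  lattice[years - min(years) + 1L] <- res
  best <- c(p = 0L, q = 0L); best_ic <- Inf
  for (p in 0:max_order) for (q in 0:max_order) {
    k <- p + q + 1  # + innovation variance
    ic <- tryCatch({
      fit <- suppressWarnings(
        arima(lattice, order = c(p, 0L, q), include.mean = FALSE,
              method = "ML"))
      stats::AIC(fit) + 2 * k * (k + 1) / max(n - k - 1, 1)
    }, error = function(e) Inf)
    better <- ic < best_ic - 1e-8 ||
      (abs(ic - best_ic) <= 1e-8 &&
       (p + q < sum(best) || (p + q == sum(best) && p < best[["p"]])))
    if (better) { best <- c(p = p, q = q); best_ic <- ic }
  }
  best
}

#' GLS linear trend with ARMA error covariance
#'
#' Regresses a metric on calendar year by generalized least squares with an
#' ARMA(p, q) correlation structure on the annual lattice (`nlme::corARMA`
#' with the year as integer position, so gap years contribute the correct
#' lag decay without imputation).  Order (0, 0) reduces exactly to ordinary
#' least squares.  Estimation is by REML by default (the better-calibrated
#' small-sample choice; `method = "ML"` is available when likelihoods must
#' be comparable across mean structures).  The slope test is the two-sided
#' t test on the GLS slope.
#'
#' @param values metric values (`NA` observations dropped).
#' @param years strictly increasing integer years.
#' @param order integer `c(p, q)`; defaults to [select_error_structure()].
#' @param min_n minimum observations required for any fit (default 5).
#' @param fallback_ols on ARMA non-convergence, refit with order (0, 0) and
#'   flag the result (`converged = FALSE`) instead of raising an error.
#' @return object of class `trend_fit`: list with `slope`, `intercept`,
#'   `se`, `p_value`, `p`, `q`, `arma_coef`, `n`, `logLik`, `converged`.
#' @examples
#' yrs <- 1984:2011
#' fit_trend(2 + 0.5 * (yrs - 1984), yrs, order = c(0, 0))$slope
#' @export
fit_trend <- function(values, years, order = NULL, min_n = 5,
                      fallback_ols = FALSE, method = c("REML", "ML")) {
  method <- match.arg(method)
  ok <- !is.na(values) & !is.na(years)
  values <- values[ok]; years <- as.integer(years[ok])
  n <- length(values)
  if (n < min_n) stop("need at least ", min_n, " observations, got ", n)
  if (any(diff(years) <= 0)) stop("years must be strictly increasing")
  if (sd(values) == 0) {
    # perfectly flat series: no trend, no evidence against the null
    return(structure(list(slope = 0, intercept = values[1], se = 0,
                          p_value = 1, p = 0L, q = 0L,
                          arma_coef = numeric(0), n = n, logLik = NA_real_,
                          converged = TRUE), class = "trend_fit"))
  }
  if (is.null(order)) order <- select_error_structure(values, years)
  p <- as.integer(order[[1]]); q <- as.integer(order[[2]])
  dat <- data.frame(value = values, year = years)
  if (p == 0L && q == 0L) {
    fit <- lm(value ~ year, data = dat)
    sm <- summary(fit)$coefficients
    out <- list(slope = sm["year", "Estimate"],
                intercept = sm["(Intercept)", "Estimate"],
                se = sm["year", "Std. Error"],
                p_value = sm["year", "Pr(>|t|)"],
                p = 0L, q = 0L, arma_coef = numeric(0),
                n = n, logLik = as.numeric(stats::logLik(fit)),
                converged = TRUE)
    return(structure(out, class = "trend_fit"))
  }
  fit <- tryCatch(
    nlme::gls(value ~ year, data = dat,
              correlation = nlme::corARMA(p = p, q = q, form = ~year),
              method = method,
              control = nlme::glsControl(maxIter = 100, msMaxIter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    if (!fallback_ols)
      stop("GLS fit with ARMA(", p, ",", q, ") errors failed: ",
           conditionMessage(fit))
    # non-convergence is reported via converged = FALSE, never silently
    out <- fit_trend(values, years, order = c(0, 0))
    out$converged <- FALSE
    out$note <- sprintf("ARMA(%d,%d) fit failed (%s); ordinary least squares",
                        p, q, conditionMessage(fit))
    return(out)
  }
  tt <- summary(fit)$tTable
  structure(list(
    slope = tt["year", "Value"],
    intercept = tt["(Intercept)", "Value"],
    se = tt["year", "Std.Error"],
    p_value = tt["year", "p-value"],
    p = p, q = q,
    arma_coef = coef(fit$modelStruct$corStruct, unconstrained = FALSE),
    n = n, logLik = as.numeric(stats::logLik(fit)),
    converged = TRUE), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> ARMA(%d,%d)  slope %.4g (se %.3g, p = %.3g), n = %d\n",
              x$p, x$q, x$slope, x$se, x$p_value, x$n))
  invisible(x)
}

#' Trend table over metric and RID series
#'
#' One GLS trend fit per (zone, class, metric) series of a long metrics
#' table, and per zone of a RID series (fitted against the interval end
#' year).  Missing values are skipped within a series; series with fewer
#' than `min_n` non-missing observations are dropped with the reason
#' recorded in the `skipped` attribute.
#'
#' @param metrics output of [metrics_for_series()] (wide) or
#'   [metrics_long()] (long), or `NULL`.
#' @param rid_tbl output of [rid_series()], or `NULL`.
#' @param alpha significance threshold for the summary columns.
#' @param adjust apply Benjamini-Hochberg correction across the table.
#' @param min_n minimum observations per series.
#' @param max_order passed to [select_error_structure()].
#' @return tibble with one row per fitted series: `zone`, `class`, `metric`,
#'   `n`, `slope`, `se`, `p_value`, `ar_order`, `ma_order`, `significant`,
#'   `direction`.
#' @export
trend_table <- function(metrics = NULL, rid_tbl = NULL, alpha = 0.05,
                        adjust = FALSE, min_n = 5, max_order = 2) {
  series <- list()
  if (!is.null(metrics)) {
    if (!"metric" %in% names(metrics)) metrics <- metrics_long(metrics)
    key <- interaction(metrics$zone, metrics$class, metrics$metric, drop = TRUE)
    for (s in split(metrics, key)) {
      series[[length(series) + 1L]] <- list(
        zone = s$zone[1], class = s$class[1], metric = s$metric[1],
        years = s$year, values = s$value)
    }
  }
  if (!is.null(rid_tbl)) {
    for (s in split(rid_tbl, rid_tbl$zone)) {
      series[[length(series) + 1L]] <- list(
        zone = s$zone[1], class = NA_character_, metric = "RID",
        years = s$year_to, values = s$RID)
    }
  }
  rows <- list(); skipped <- list()
  for (s in series) {
    ok <- !is.na(s$values)
    if (sum(ok) < min_n) {
      skipped[[length(skipped) + 1L]] <- sprintf(
        "%s/%s/%s: only %d non-missing observations",
        s$zone, s$class, s$metric, sum(ok))
      next
    }
    ord <- select_error_structure(s$values[ok], s$years[ok],
                                  max_order = max_order)
    fit <- fit_trend(s$values[ok], s$years[ok], order = ord,
                     fallback_ols = TRUE)
    if (!fit$converged)
      skipped[[length(skipped) + 1L]] <- sprintf(
        "%s/%s/%s: %s", s$zone, s$class, s$metric, fit$note)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      zone = s$zone, class = s$class, metric = s$metric,
      n = fit$n, slope = fit$slope, se = fit$se, p_value = fit$p_value,
      ar_order = fit$p, ma_order = fit$q)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no series with enough observations to fit")
  if (adjust) out$p_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < alpha
  out$direction <- ifelse(!out$significant, "ns",
                          ifelse(out$slope > 0, "increase", "decrease"))
  attr(out, "skipped") <- unlist(skipped)
  out
}
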