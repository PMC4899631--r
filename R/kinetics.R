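#' Decay time series of antibody-secreting cells
#'
#' @param time timepoints in days, strictly increasing.
#' @param count positive cell counts at each timepoint.
#' @return tibble of class `decay_series` with columns `time`, `count` and
#'   `ratio` (`count / count[1]`, so `ratio[1] = 1`).
#' @export
decay_series <- function(time, count) {
  if (length(time) != length(count)) abort("`time` and `count` lengths differ")
  if (length(time) == 0L) stop_field("time", "must be non-empty")
  if (any(diff(time) <= 0)) stop_field("time", "must be strictly increasing")
  if (any(!is.finite(count)) || any(count <= 0)) {
    stop_field("count", "must be positive")
  }
  out <- tibble(time = as.numeric(time), count = as.numeric(count),
                ratio = as.numeric(count) / count[1])
  class(out) <- c("decay_series", class(out))
  out
}

#' Estimate a half-life by log-linear regression
#'
#' Fits ordinary least squares to `ln(count / count_initial)` against time;
#' the half-life is `ln(2) / |slope|`. By default the intercept is free
#' (measurement noise at the first timepoint argues against forcing the fit
#' through ratio 1); set `through_origin = TRUE` to constrain it.
#'
#' @param series a [decay_series()] (or anything `decay_series()` accepts via
#'   `time`/`count` columns).
#' @param through_origin force the regression line through `ln(ratio) = 0` at
#'   `time = 0`.
#' @return list of class `half_life_fit`: `slope` (per day), `slope_se`,
#'   `t_half` (days; `NA` with `undefined = TRUE` when the slope is
#'   non-negative), `r_squared`, `n`, `through_origin` and the underlying
#'   `fit`.
#' @export
estimate_half_life <- function(series, through_origin = FALSE) {
  if (!inherits(series, "decay_series")) {
    series <- decay_series(series$time, series$count)
  }
  if (nrow(series) < 3L) abort("need at least 3 timepoints")
  y <- log(series$ratio)
  t <- series$time
  fit <- if (through_origin) lm(y ~ t + 0) else lm(y ~ t)
  # summary.lm warns on exact (noiseless) fits; a zero standard error is fine
  sm <- suppressWarnings(summary(fit))
  slope <- coef(fit)[["t"]]
  slope_se <- sm$coefficients["t", "Std. Error"]
  undefined <- slope >= 0
  structure(
    list(slope = slope, slope_se = slope_se,
         t_half = if (undefined) NA_real_ else log(2) / abs(slope),
         r_squared = sm$r.squared, n = nrow(series),
         through_origin = through_origin, undefined = undefined, fit = fit),
    class = "half_life_fit")
}

#' @export
print.half_life_fit <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("<half_life_fit> slope %.4g/day (non-negative): t1/2 undefined\n",
                x$slope))
  } else {
    cat(sprintf("<half_life_fit> t1/2 = %.1f days (slope %.4g/day, R^2 %.3f, n=%d)\n",
                x$t_half, x$slope, x$r_squared, x$n))
  }
  invisible(x)
}

#' Compare the decay slopes of two time courses
#'
#' Two-sided t-test on the difference between the two regression slopes using
#' the pooled residual variance of the two fits:
#' `t = (b1 - b2) / sqrt(s_p^2 (1/Sxx1 + 1/Sxx2))` with
#' `s_p^2 = (RSS1 + RSS2) / (n1 + n2 - 4)` degrees of freedom — the classic
#' test for equality of two regression slopes.
#'
#' @param a,b [decay_series()] objects.
#' @param through_origin passed to [estimate_half_life()].
#' @return list with `t_statistic`, `df`, `p_value`, `slope_a`, `slope_b`.
#' @export
compare_decay_slopes <- function(a, b, through_origin = FALSE) {
  fa <- estimate_half_life(a, through_origin = through_origin)
  fb <- estimate_half_life(b, through_origin = through_origin)
  diff <- fa$slope - fb$slope
  df <- fa$n + fb$n - 4L
  sxx <- function(f) {
    t <- f$fit$model$t
    if (f$through_origin) sum(t^2) else sum((t - mean(t))^2)
  }
  rss <- sum(stats::residuals(fa$fit)^2) + sum(stats::residuals(fb$fit)^2)
  s2 <- rss / df
  se <- sqrt(s2 * (1 / sxx(fa) + 1 / sxx(fb)))
  if (se == 0) {
    if (diff == 0) {
      return(list(t_statistic = 0, df = df, p_value = 1,
                  slope_a = fa$slope, slope_b = fb$slope))
    }
    abort("degenerate variance: both fits are exact but slopes differ")
  }
  tstat <- diff / se
  list(t_statistic = tstat, df = df,
       p_value = 2 * pt(-abs(tstat), df),
       slope_a = fa$slope, slope_b = fb$slope)
}

#' Virus neutralization titre from an OD dilution series
#'
#' The 50% specific-signal threshold is
#' `(OD_virus_control - OD_cell_control) / 2 + OD_cell_control`. Scanning
#' from the lowest dilution, the titre is the last dilution in the initial
#' run of readings below the threshold (the highest dilution at which fewer
#' than half of the cells were infected). Non-monotone series — readings
#' dropping below the threshold again after the initial run — are flagged.
#'
#' @param dilutions reciprocal serum dilutions, strictly increasing.
#' @param od OD450 readings, one per dilution.
#' @param od_virus virus-control OD450 (no serum; must exceed `od_cell`).
#' @param od_cell cell-control OD450 (no virus).
#' @return list of class `neut_titre`: `titre` (reciprocal dilution; `NA`
#'   when even the first dilution fails to neutralize), `threshold`,
#'   `below_first_dilution`, `non_monotone`.
#' @export
neutralization_titre <- function(dilutions, od, od_virus, od_cell) {
  if (length(dilutions) != length(od)) abort("`dilutions` and `od` lengths differ")
  if (any(diff(dilutions) <= 0)) stop_field("dilutions", "must be strictly increasing")
  if (any(od < 0) || od_virus < 0 || od_cell < 0) {
    stop_field("od", "readings must be non-negative")
  }
  if (od_virus <= od_cell) {
    abort("no assay window: virus-control OD must exceed cell-control OD")
  }
  threshold <- (od_virus - od_cell) / 2 + od_cell
  below <- od < threshold
  run <- 0L
  while (run < length(below) && below[run + 1L]) run <- run + 1L
  non_monotone <- any(below[seq_along(below) > run])
  structure(
    list(titre = if (run >= 1L) dilutions[run] else NA_real_,
         threshold = threshold,
         below_first_dilution = run == 0L,
         non_monotone = non_monotone),
    class = "neut_titre")
}

#' @export
print.neut_titre <- function(x, ...) {
  if (x$below_first_dilution) {
    cat(sprintf("<neut_titre> below first dilution (threshold OD %.3f)\n",
                x$threshold))
  } else {
    cat(sprintf("<neut_titre> 1:%g (threshold OD %.3f)%s\n", x$titre,
                x$threshold,
                if (x$non_monotone) " [non-monotone series]" else ""))
  }
  invisible(x)
}

#' Read decay time courses from TSV
#'
#' Expects columns `series_id`, `day`, `count`.
#'
#' @param path TSV file.
#' @return named list of [decay_series()] objects, one per `series_id`.
#' @export
read_decay_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("series_id", "day", "count") %in% names(df)))
  lapply(split(df, df$series_id), function(d) {
    d <- d[order(d$day), ]
    decay_series(d$day, d$count)
  })
}

#' Read an OD neutralization table from TSV
#'
#' Expects columns `sample_id`, `dilution`, `od450`; control rows carry
#' `sample_id` values `"virus_control"` and `"cell_control"` (their dilution
#' is ignored).
#'
#' @param path TSV file.
#' @return tibble of titres, one row per sample (`sample_id, titre,
#'   threshold, below_first_dilution, non_monotone`).
#' @export
read_od_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("sample_id", "dilution", "od450") %in% names(df)))
  odv <- df$od450[df$sample_id == "virus_control"][1]
  odc <- df$od450[df$sample_id == "cell_control"][1]
  if (is.na(odv) || is.na(odc)) abort("missing virus_control / cell_control rows")
  samples <- df[!df$sample_id %in% c("virus_control", "cell_control"), ]
  bind_rows(lapply(split(samples, samples$sample_id), function(d) {
    d <- d[order(d$dilution), ]
    tt <- neutralization_titre(d$dilution, d$od450, odv, odc)
    tibble(sample_id = d$sample_id[1], titre = tt$titre,
           threshold = tt$threshold,
           below_first_dilution = tt$below_first_dilution,
           non_monotone = tt$non_monotone)
  }))
}
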