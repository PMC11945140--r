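# Model-performance statistics: mean relative difference, root mean square
# error, normalized RMSE, and the four-category NRMSE classification used
# to grade crop-model skill.

#' Mean relative difference (percent)
#'
#' Mean of `(P - O) / O * 100` over paired predictions and observations.
#' Pairs with a zero observation are undefined and are excluded with a
#' warning (sampling schedules that start at anthesis produce zero
#' observations on day 0).
#'
#' @param pred,obs numeric vectors of equal length, paired by day.
#' @return MRD in percent (signed).
#' @export
mrd <- function(pred, obs) {
  stopifnot(length(pred) == length(obs), length(obs) >= 1)
  usable <- obs != 0
  if (!all(usable)) {
    warning(sum(!usable), " pair(s) with zero observation excluded from MRD")
  }
  if (!any(usable)) stop("no usable pairs (all observations are zero)")
  mean((pred[usable] - obs[usable]) / obs[usable]) * 100
}

#' Root mean square error
#'
#' @param pred,obs numeric vectors of equal length, paired by day.
#' @return RMSE in the units of the variable.
#' @export
rmse <- function(pred, obs) {
  stopifnot(length(pred) == length(obs), length(obs) >= 1)
  sqrt(mean((pred - obs)^2))
}

#' Normalized root mean square error (percent)
#'
#' RMSE divided by the observation mean, in percent.
#'
#' @param pred,obs numeric vectors of equal length, paired by day.
#' @return NRMSE in percent.
#' @export
nrmse <- function(pred, obs) {
  o_avg <- mean(obs)
  if (o_avg == 0) stop("observation mean is zero; NRMSE undefined")
  rmse(pred, obs) / o_avg * 100
}

#' Classify model performance from NRMSE
#'
#' Standard agronomic bins: excellent (< 10%), good (10-20%), moderate
#' (20-30%), poor (>= 30%); boundaries belong to the higher bin.
#'
#' @param nrmse NRMSE in percent; >= 0.
#' @return One of `"excellent", "good", "moderate", "poor"`. Vectorized.
#' @export
classify_nrmse <- function(nrmse) {
  if (any(nrmse < 0)) stop("NRMSE cannot be negative")
  cut(nrmse, breaks = c(-Inf, 10, 20, 30, Inf), right = FALSE,
      labels = c("excellent", "good", "moderate", "poor")) |>
    as.character()
}

#' Evaluate predictions against an observation set
#'
#' Pairs a simulated quality series with observations by exact `day_index`
#' match (no interpolation) and computes MRD, RMSE, NRMSE and the
#' performance category.
#'
#' @param qs quality series data.frame (or any data.frame holding
#'   `day_index` and the variable's column).
#' @param obs an `observation_set` (see [make_observations()]).
#' @return Object of class `eval_result`: list with `variable, n, mrd_pct,
#'   rmse, nrmse_pct, category`.
#' @export
evaluate_predictions <- function(qs, obs) {
  stopifnot(inherits(obs, "observation_set"))
  col <- c(GPA = "gpa", GSA = "gsa", GASA = "gasa", GAPA = "gapa",
           GNA = "gna")[obs$variable]
  if (is.na(col) || !col %in% names(qs)) {
    stop("quality series lacks a column for variable ", obs$variable)
  }
  idx <- match(obs$samples$day_index, qs$day_index)
  if (anyNA(idx)) {
    stop("observation days missing from the simulated series: ",
         paste(obs$samples$day_index[is.na(idx)], collapse = ", "))
  }
  pred <- qs[[col]][idx]
  o <- obs$samples$value
  nr <- nrmse(pred, o)
  structure(list(variable = obs$variable, n = length(o),
                 mrd_pct = mrd(pred, o), rmse = rmse(pred, o),
                 nrmse_pct = nr, category = classify_nrmse(nr)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "<eval_result> %s: n = %d, MRD = %.2f%%, RMSE = %.3f, NRMSE = %.2f%% (%s)\n",
    x$variable, x$n, x$mrd_pct, x$rmse, x$nrmse_pct, x$category))
  invisible(x)
}
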