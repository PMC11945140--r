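# Daily water- and nitrogen-stress factors shared by the protein and
# starch modules. Both are unitless indices in [0, 1]; 1 = unstressed.

#' Water-stress factor
#'
#' The ratio of actual to potential transpiration, clamped to `[0, 1]`.
#' Zero transpirative demand (`tp = 0`) is treated as no stress (factor 1),
#' the standard crop-model convention.
#'
#' @param ta actual transpiration, mm/day.
#' @param tp potential transpiration, mm/day.
#' @return Water-stress factor in `[0, 1]`. Vectorized.
#' @examples
#' water_stress(3.2, 4.0)  # 0.8
#' @export
water_stress <- function(ta, tp) {
  if (any(ta < 0) || any(tp < 0)) {
    stop("transpiration values must be nonnegative")
  }
  fw <- ifelse(tp == 0, 1, pmin(1, pmax(0, ta / tp)))
  fw
}

#' Nitrogen-stress factor
#'
#' Linear ramp of the plant nitrogen concentration between the minimum
#' (`mnp`, factor 0) and critical (`cnp`, factor 1) concentrations:
#' `min(1, (anp - mnp) / (cnp - mnp))`, additionally clamped below at 0 so
#' the factor stays in its documented `[0, 1]` range when the plant drops
#' below the minimum concentration.
#'
#' @param anp plant nitrogen concentration, fraction.
#' @param cnp critical plant nitrogen concentration, fraction.
#' @param mnp minimum plant nitrogen concentration, fraction.
#' @return Nitrogen-stress factor in `[0, 1]`. Vectorized.
#' @export
nitrogen_stress <- function(anp, cnp, mnp) {
  if (any(cnp <= mnp)) {
    stop("critical N concentration must exceed the minimum (cnp > mnp)")
  }
  pmin(1, pmax(0, (anp - mnp) / (cnp - mnp)))
}
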