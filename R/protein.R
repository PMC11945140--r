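# Grain-protein module: stress-modulated nitrogen-to-protein conversion.

#' Grain-protein module parameters
#'
#' Defaults are the calibrated values for foxtail millet: baseline
#' conversion factor `npf0 = 5.83` and stress correction `delta = 0.18`,
#' so the daily conversion factor ranges over `[5.83, 6.01]`.
#'
#' @param npf0 baseline nitrogen-to-protein conversion factor,
#'   dimensionless; > 0.
#' @param delta correction added under unstressed conditions,
#'   dimensionless; >= 0.
#' @return Object of class `protein_params`.
#' @export
protein_params <- function(npf0 = 5.83, delta = 0.18) {
  stopifnot(npf0 > 0, delta >= 0)
  structure(list(npf0 = npf0, delta = delta), class = "protein_params")
}

#' Daily nitrogen-to-protein conversion factor
#'
#' `NPF = delta * min(fw, fn) + npf0`: the conversion factor rises from
#' `npf0` under full stress to `npf0 + delta` when neither water nor
#' nitrogen limits the plant. The binding (smaller) stress factor governs.
#'
#' @param fw water-stress factor in `[0, 1]`.
#' @param fn nitrogen-stress factor in `[0, 1]`.
#' @param params a [protein_params()].
#' @return Conversion factor, dimensionless; in `[npf0, npf0 + delta]`.
#'   Vectorized over `fw`/`fn`.
#' @examples
#' npf(1, 1)  # 6.01 with the calibrated defaults
#' @export
npf <- function(fw, fn, params = protein_params()) {
  if (any(fw < 0 | fw > 1) || any(fn < 0 | fn > 1)) {
    stop("stress factors must lie in [0, 1]")
  }
  params$delta * pmin(fw, fn) + params$npf0
}

#' Daily grain protein accumulation
#'
#' `GPA[i] = GNA[i] * NPF[i]`, with the conversion factor computed from the
#' same day's water and nitrogen stress (no smoothing or lag). Day 0
#' (anthesis) is evaluated too so cumulative plots start at anthesis.
#'
#' @param series a [crop_state_series()].
#' @param params a [protein_params()].
#' @return data.frame with columns `day_index, fw, fn, npf, gpa`
#'   (gpa in kg/ha), aligned with the input days.
#' @export
protein_accumulation <- function(series, params = protein_params()) {
  stopifnot(inherits(series, "crop_state_series"))
  d <- series$days
  fw <- water_stress(d$ta, d$tp)
  fn <- nitrogen_stress(d$anp, d$cnp, d$mnp)
  npf_i <- npf(fw, fn, params)
  data.frame(day_index = d$day_index, fw = fw, fn = fn,
             npf = npf_i, gpa = d$gna * npf_i)
}
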