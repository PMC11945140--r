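# Independent single-pass recomputation of the daily quality chain,
# written as a plain scalar day loop straight from the model definitions.
# Deliberately shares no code with the package's vectorized simulator; used
# as the equivalence oracle.

oracle_quality <- function(series, pp = table3_protein(),
                           sp_ = table3_starch(),
                           part = table3_partition()) {
  d <- series$days
  n <- nrow(d)
  SP <- series$sp
  NG <- series$ng
  gdd_am <- series$gdd_am
  out <- data.frame(day_index = d$day_index, gdd = d$gdd,
                    fw = NA_real_, fn = NA_real_, npf = NA_real_,
                    gpa = NA_real_, gcp = NA_real_, gct = NA_real_,
                    gca = NA_real_, f_gdd = NA_real_, f_t = NA_real_,
                    eact = NA_real_, istr = NA_real_, igsa = NA_real_,
                    gsa = NA_real_, ra = NA_real_, gasa = NA_real_,
                    gapa = NA_real_)
  igsa_prev <- sp_$igsa0
  for (i in seq_len(n)) {
    fw <- if (d$tp[i] == 0) 1 else min(1, max(0, d$ta[i] / d$tp[i]))
    fn <- min(1, max(0, (d$anp[i] - d$mnp[i]) / (d$cnp[i] - d$mnp[i])))
    npf_i <- pp$delta * min(fw, fn) + pp$npf0
    gpa <- d$gna[i] * npf_i

    if (i == 1) {
      gcp <- 0; gct <- 0
    } else {
      dt <- d$topwt[i] - d$topwt[i - 1]
      dv <- d$vwt[i] - d$vwt[i - 1]
      if (d$gdd[i] < sp_$gdd_m) {
        gcp <- max(0, dt - dv); gct <- 0
      } else {
        gcp <- max(0, dt); gct <- max(0, -dv)
      }
    }
    gca <- 1e6 * (gcp + gct) / (SP * NG)

    f_gdd <- if (d$gdd[i] <= sp_$gdd_m) {
      (d$gdd[i] / sp_$gdd_m) * exp(sp_$gamma * (sp_$gdd_m - d$gdd[i]))
    } else {
      (gdd_am - d$gdd[i]) / (gdd_am - sp_$gdd_m)
    }
    f_gdd <- min(1, max(0, f_gdd))

    t <- d$tavg[i]
    f_t <- if (t < sp_$tb || t > sp_$tm) {
      0
    } else if (t < sp_$tol) {
      sin((t - sp_$tb) / (sp_$tol - sp_$tb) * pi / 2)
    } else if (t < sp_$toh) {
      1
    } else {
      sin((sp_$tm - t) / (sp_$tm - sp_$toh) * pi / 2)
    }

    eact <- f_gdd * f_t * fw * fn
    istr <- sp_$istr_m * eact * gca / (sp_$km + gca)
    if (sp_$cap_rate_to_supply) istr <- min(istr, gca)
    igsa <- igsa_prev + istr
    igsa_prev <- igsa
    gsa <- SP * NG * igsa * 1e-6

    ra <- if (d$gdd[i] > 0) {
      min(1, max(0, (part$alpha * log(d$gdd[i]) - part$beta) * fn))
    } else 0

    out[i, c("fw", "fn", "npf", "gpa", "gcp", "gct", "gca", "f_gdd",
             "f_t", "eact", "istr", "igsa", "gsa", "ra", "gasa",
             "gapa")] <-
      c(fw, fn, npf_i, gpa, gcp, gct, gca, f_gdd, f_t, eact, istr,
        igsa, gsa, ra, gsa * ra, gsa * (1 - ra))
  }
  out
}
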