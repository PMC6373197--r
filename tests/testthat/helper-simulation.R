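# Shared simulation study designs for the calibration and recovery checks.

identity_correlations <- function() {
  list(home_cage = fosconnect::factor_correlation(),
       context_only = fosconnect::factor_correlation(),
       recall = fosconnect::factor_correlation(),
       extinction = fosconnect::factor_correlation())
}

flat_fold_changes <- function() {
  matrix(1, 4, 16, dimnames = list(fosconnect::fos_groups(),
                                   fosconnect::region_codes()))
}

# 99% binomial band around a target proportion.
binomial_band <- function(p, n) {
  half <- stats::qnorm(0.995) * sqrt(p * (1 - p) / n)
  c(p - half, p + half)
}
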