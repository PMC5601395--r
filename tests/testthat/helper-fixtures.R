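# Shared fixtures: a "fast" parameter bundle whose constant-volume phase ends
# within days (tiny interstitial capacity), so engine behaviour around the
# growth transition can be exercised at short horizons.

# Override any athero_params() field; phi defaults to 5e-4 here (early
# transition) unless explicitly overridden.
fast_params <- function(...) {
  p <- default_params()
  a <- unclass(p$athero)
  over <- list(...)
  a[names(over)] <- over
  if (!"phi" %in% names(over)) a$phi <- 5e-4
  p$athero <- do.call(athero_params, a)
  p
}

final_pct_tav <- function(result) {
  result$grid$pct_tav[nrow(result$grid)]
}
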