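# Internal helpers shared across modules.

# Left-closed, right-open band lookup: breaks c(b1,...,bk) define bands
# (-Inf,b1), [b1,b2), ..., [bk,Inf); returns 1..k+1. Top band closed above.
band_lookup <- function(x, breaks) {
  findInterval(x, breaks) + 1L
}

# round() uses banker's rounding; reported risk ratios round half UP, as in
# conventional table formatting. Small epsilon guards binary representation
# of values like 0.45 that sit just under the half boundary.
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ohra_stop <- function(fmt, ..., class = "ohra_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "ohra_error")))
}

# Stable 32-bit polynomial hash of a string; used to derive per-stratum
# simulation seeds so adding a stratum never perturbs the draws of another.
stable_hash <- function(key) {
  h <- 0
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

derive_seed <- function(global_seed, key) {
  as.integer((as.numeric(global_seed) * 1000003 + stable_hash(key)) %% 2147483647)
}

# MD5 checksum of a configuration list over its canonical JSON serialization;
# embedded in every result table so subjective rating tables are traceable.
config_checksum <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}
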