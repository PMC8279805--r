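# Rounding helpers. Display rounding is half-away-from-zero (commercial
# rounding), not the IEEE round-half-even of base round().

round_dollar <- function(x) sign(x) * floor(abs(x) + 0.5)

round_nearest <- function(x, unit) sign(x) * floor(abs(x) / unit + 0.5) * unit

`%||%` <- function(a, b) if (is.null(a)) b else a

as_prob_fn <- function(x) {
  if (is.function(x)) return(x)
  stopifnot(is.numeric(x), length(x) == 1L)
  force(x)
  function(scenario) x
}

as_cost_fn <- function(x) {
  if (is.function(x)) return(x)
  stopifnot(is.numeric(x), length(x) == 1L)
  force(x)
  function(params) x
}
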