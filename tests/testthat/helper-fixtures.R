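# Shared fixtures, built once per test run.

.fx <- new.env(parent = emptyenv())

# default emphysema phantom (f = 0.25) plus its segmentations
default_phantom <- function() {
  if (is.null(.fx$ph)) {
    .fx$ph <- make_ct_phantom(
      phantom_spec(shape = c(96L, 96L, 96L), emphysema_fraction = 0.25,
                   seed = 7L))
    .fx$lung <- segment_lungs(.fx$ph$volume)
    .fx$airway <- segment_airways(.fx$ph$volume)
    .fx$refined <- refine_lung_mask(.fx$lung, .fx$airway, 2,
                                    .fx$ph$volume$spacing)
  }
  .fx
}

# analytic FEV_x:FVC ratio of a multi-exponential preset whose trace runs
# to `duration` (FVC is read at trace end) -- independent of the trace
# analysis code
analytic_ratio <- function(x, fractions, tau, duration = 8 * max(tau)) {
  num <- sum(fractions * (1 - exp(-x / tau)))
  den <- sum(fractions * (1 - exp(-duration / tau)))
  num / den
}

quiet_lmer <- function(expr) suppressWarnings(suppressMessages(expr))
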