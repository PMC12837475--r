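# Shared fixtures built in code.

# The five-source budget whose relative uncertainties are proportional to
# the square roots of the published shares (which sum to exactly 1.000),
# so uc_rel = 0.125 and the shares round-trip.
five_source_u <- function(uc = 0.125) {
  shares <- c("Sample Weighing" = 0.112, "Extractor" = 0.344,
              "zero-card Calibration" = 0.061, "Curve Fitting" = 0.006,
              "Lab Card" = 0.477)
  uc * sqrt(shares)
}

five_source_budget <- function(uc = 0.125) {
  assemble_budget(as.list(five_source_u(uc)))
}

# Independent oracle for the root-sum-of-squares combination: an explicit
# summation loop, no vectorized sum/sqrt shortcuts shared with the
# implementation path.
combine_oracle <- function(u, c = rep(1, length(u))) {
  total <- 0
  for (i in seq_along(u)) total <- total + (c[i] * u[i])^2
  sqrt(total)
}

random_budget <- function(n_max = 20) {
  n <- sample.int(n_max, 1)
  u <- stats::runif(n, 0, 0.2)
  c <- stats::runif(n, 0.1, 3)
  list(u = u, c = c,
       components = Map(function(i) {
         uncertainty_component(paste0("src_", i), u = u[i], c = c[i])
       }, seq_len(n)))
}
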