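# Random but reproducible parameter draws over the simulated ranges
# (a0 in [0.01, 1], learning rates in [0, 1], hm in [0, 0.1], h0 = 1,
# am = 1) used by the property-style tests.
draw_predators <- function(n, seed = 42L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    a0 <- runif(1, 0.01, 1)
    fr_predator(a0 = a0, am = 1, la = runif(1, 0, 1),
                h0 = 1, hm = runif(1, 0, 0.1), lh = runif(1, 0, 1))
  })
}

# Derivative profile built directly from (offered, d2) pairs, for unit
# tests of the inflection locator.
fake_profile <- function(offered, d2) {
  structure(list(offered = offered, d1 = rep(NA_real_, length(d2)),
                 d2 = d2, normalized_d2 = d2,
                 offered_range = diff(range(offered)), consumed_range = 1),
            class = "fr_derivatives")
}

final_consumed <- function(trajectory) {
  trajectory$n_consumed[nrow(trajectory)]
}
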