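# Shared fixtures: coarse but adequate integration settings for unit tests.

quick_conceptual <- function(params = conceptual_params(), dt = 0.02,
                             t_end = 480) {
  integrate_dde(params, t_span = c(0, t_end), dt = dt)
}

quick_comprehensive <- function(params = comprehensive_params(), dt = 0.05,
                                t_end = 700) {
  integrate_dde(params, t_span = c(0, t_end), dt = dt)
}

# small sweep grids used where the full default grid would be wasteful
small_scales <- function(n = 5, lo = 0.35, hi = 1)
  exp(seq(log(lo), log(hi), length.out = n))
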