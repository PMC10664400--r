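# Shared fixtures and small utilities for the test suite.

twocomp_truth <- c(p1 = 0.5, p2 = 0.15, x1_0 = 10)
mh_truth <- c(k = 2, kI = 50)

mh_grid <- function(n = 40, tf = 50) seq(0, tf, length.out = n)

mh_bounds <- list(k = c(0.1, 20), kI = c(5, 500))

# informative constant feed for the chemostat examples
mh_input <- function() input_constant(20)

rel_diff <- function(a, b, floor = 1e-12) {
  max(abs(a - b) / pmax(abs(b), floor))
}

# a minimal valid model JSON (twocomp) for parser tests
twocomp_json <- function() {
  paste0('{"name":"twocomp",',
         '"states":[{"name":"x1","ic":{"known":false}},',
         '{"name":"x2","ic":{"known":true,"value":0}}],',
         '"parameters":[{"name":"p1","known":false},{"name":"p2","known":false}],',
         '"inputs":[],"constants":{},',
         '"odes":{"x1":"-p1*x1","x2":"p1*x1 - p2*x2"},',
         '"outputs":{"y":"x2"}}')
}
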