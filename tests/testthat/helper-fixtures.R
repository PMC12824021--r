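# shared test fixtures: parameter sets built in code

ad1_params <- function() {
  mr_params(c1 = 2.6970, D1 = 15.1322, D2 = 0.9272,
            K1 = 2.1722, K2 = 0.9338, theta = 5.56)
}

isotropic_params <- function(c1 = 10) {
  mr_params(c1 = c1, D1 = 0, D2 = 0, K1 = 0, K2 = 1, theta = 0)
}

# incompressible stretch triple from in-plane stretches
lam_r <- function(lc, la) 1 / (lc * la)

# strain energy as a function of the two in-plane stretches only
w_hat <- function(params, lc, la) {
  strain_energy(params, invariants_from_stretches(lc, la, lam_r(lc, la),
                                                  params$theta))
}

# run the CLI surface without spilling its stdout into the test log
quiet_cli <- function(args) {
  status <- NULL
  utils::capture.output(status <- aortafit_cli(args))
  status
}
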