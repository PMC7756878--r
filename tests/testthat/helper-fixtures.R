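# shared fixture builders for the test suite

# vitals in the [age, habitat, transition] layout used by the CMR code
make_cmr_vitals <- function(phi_fl = c(0.2, 0.15), phi_br = c(0.5, 0.55),
                            psi_fl = c(0.2, 0.3), psi_br = c(0.05, 0.1),
                            n_trans = 3) {
  phi <- array(NA_real_, c(2, 2, n_trans))
  for (t in seq_len(n_trans)) {
    phi[1, , t] <- phi_fl
    phi[2, , t] <- phi_br
  }
  list(phi = phi, psi = rbind(psi_fl, psi_br, deparse.level = 0))
}

random_vital_rates <- function() {
  vital_rates(b = runif(2), f = runif(2, 0, 5), phi_fl = runif(2),
              phi_br = runif(2), psi_fl = runif(2), psi_br = runif(2))
}

# a tiny simulated dataset for IO / fitting smoke tests
tiny_sim <- function(seed = 42, years = 6, n_core = 20, n_peripheral = 8,
                     n_mark_fl = 12, n_mark_br = 6, ...) {
  set.seed(seed)
  ls <- generate_landscape(n_core = n_core, n_peripheral = n_peripheral)
  scn <- sim_scenario(years = years, n_mark_fl = n_mark_fl,
                      n_mark_br = n_mark_br, ...)
  simulate_dataset(ls, scn)
}
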