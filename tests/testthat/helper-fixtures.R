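# shared fixtures: all synthetic, built in code

# small-gradient deflation used for the approximation-error demonstrations
small_gradient_spec <- function(P_f = 0.01) {
  vesicle_spec(r0 = nm_to_cm(100),
               c_in0 = mM_to_molcm3(290),
               c_out = mM_to_molcm3(300),
               P_f = P_f)
}

# typical stopped-flow challenge (external osmolarity roughly doubled),
# the condition used for parameter-recovery checks
challenge_spec <- function(P_f = 0.01) {
  vesicle_spec(r0 = nm_to_cm(100),
               c_in0 = mM_to_molcm3(290),
               c_out = mM_to_molcm3(590),
               P_f = P_f)
}

# random but physically sensible vesicle specs for property sweeps
random_vesicle_spec <- function() {
  r0 <- nm_to_cm(stats::runif(1, 30, 200))
  c_in0 <- mM_to_molcm3(stats::runif(1, 100, 400))
  # shrinkage and moderate swelling, never crossing c_out <= 0
  c_out <- c_in0 * stats::runif(1, 0.5, 3)
  vesicle_spec(r0, c_in0, c_out, P_f = 10^stats::runif(1, -3, -1))
}
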