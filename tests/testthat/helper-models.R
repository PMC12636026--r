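# Study parameterizations used across tests: the cross-linked and
# non-cross-linked trimer models (fixed tau_RG/a/D, fitted tau_RL,
# tau_M^SS; default order-parameter and electron-spin block).

kh2_20x_model <- function() {
  relaxation_model(
    second_sphere_params(q_ss = 2, r_ss_A = 3.6, tau_M_ss = 5.0e-9,
                         tau_RG = 7e-9, tau_RL = 318e-12, S2 = 0.5),
    outer_sphere_params(a_A = 4, D = 2.3e-10),
    electron_spin_params())
}

mb12_model <- function() {
  relaxation_model(
    second_sphere_params(q_ss = 2, r_ss_A = 3.6, tau_M_ss = 3.0e-9,
                         tau_RG = 5e-9, tau_RL = 184e-12, S2 = 0.5),
    outer_sphere_params(a_A = 4, D = 2.3e-10),
    electron_spin_params())
}
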