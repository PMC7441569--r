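{
  "R1": 12, "wd": 3, "La": 250, "R3": 150,
  "mu_f": 1e-3, "rho_f": 1000,
  "zeta": 0.8, "k_s": 2e-14,
  "mu_s": 4, "nu": 0.45, "rho_s": 1000,
  "b1": 1, "f": 10, "c": 1,
  "D": 1.4e-6,
  "r_sas": 0.01, "r_par": 10
}
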