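{
  "species1": { "var_direct": 1, "var_associate": 0.5, "rho_va": -0.5,
                "eta": 0.5, "omega": 0, "pure_design_h2": 0.6 },
  "species2": { "var_direct": 1, "var_associate": 0.1, "rho_va": -0.5,
                "eta": 0.5, "omega": 0, "pure_design_h2": 0.6 },
  "var_va_12": 0.05,
  "var_va_21": 0.25,
  "rho_va12_va21": -0.5,
  "var_plot_error_mixture": 2
}
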