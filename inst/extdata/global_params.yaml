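# Shared (population-level) kinetic constants of the vaccination model.
# Rates are per hour; h_P is in cells. Any key may be overridden; keys
# match the arguments of psavax::global_params().
k_i: 0.06        # DC maturation after vaccine uptake
n_V: 1           # vaccine cells per matured DC
V_p: 0           # natural influx of mature DCs
k_m: 0.027       # DC migration, skin -> lymph node
alpha_l: 0.03    # fraction of presenting DCs entering the lymph node
k_CR: 0.027      # exhaustion of mature DCs
mu_D: 0.014      # death of exhausted DCs
a_R: 0.003       # regulatory-cell recruitment by exhausted DCs
mu_R: 0.03       # regulatory-cell death
a_C: 0.38        # effector recruitment by mature DCs
mu_C: 0.007      # effector death
k_R: 6.0e-7      # effector inactivation by regulatory cells
h_P: 1.0e+8      # effector-efficacy damping coefficient
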