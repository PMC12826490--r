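# Default kinetic parameter set (rates in hr^-1 unless noted).
# Literature-ranged parameters are set to package defaults inside the published
# ranges; see the methods vignette for the rationale behind each point value.
D: 360            # ligand diffusion, um^2 hr^-1 (published range 36 - 360000)
k_ec: 6           # complex internalization
k_on: 6.0e+22     # ligand-receptor binding, mol^-1 um^3 hr^-1 (range 6e22 - 6e25)
k_off: 6          # complex dissociation
R0: 6.7e-22       # free receptor density without ligand, mol um^-2
k_er: 0.6         # ligand-independent receptor turnover (range 0.6 - 6)
alpha_rec: 0.7    # recycled fraction of internalized complexes (range 0.45 - 0.7)
alpha_deg: 0.3    # degraded fraction of internalized complexes (range 0.3 - 0.55)
k_rec: 2.3        # recycling rate
k_deg: 2.3        # degradation rate
k_d: 2.3          # dpERK degradation
V0: 2.0e-21       # reference ligand secretion flux, mol um^-2 hr^-1
Q_r: 4.0e-22      # receptor production, mol um^-2 hr^-1
k_s: 1            # dpERK production
H: 0.5            # perivitelline space thickness, um
gamma_STY: 5.0e+4   # calibrated STY inhibitor strength (500 x 10^2)
gamma_KEK1: 1.0e+3  # calibrated KEK1 inhibitor strength (10 x 10^2)
k_STY: 1          # STY production from signal
k_dSTY: 2.3       # STY degradation
k_KEK1: 1         # KEK1 production from signal
k_dKEK1: 2.3      # KEK1 degradation
K_kek: ~          # KEK1 feedback normalization, mol um^-2 (default derived: (k_KEK1/k_dKEK1)*(k_s/k_d)*R0)
K_sty: ~          # STY feedback normalization, mol um^-2 (same rule with k_STY)
receptor_binding_sign: -1   # -1: binding is a receptor loss term; +1: literal typeset variant
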