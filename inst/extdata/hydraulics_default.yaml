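# Default hydraulic configuration. The radial-conductivity (kr) table is a
# SYNTHETIC PLACEHOLDER: order-of-magnitude values consistent with
# published grapevine fine-root Lpr (~1e-7 m s-1 MPa-1, converted to flux
# per unit surface per cm head per day), with age-dependent suberization
# classes. Replace with measured values for any quantitative use.
# kx power law: kx(d) = alpha * d^beta, d in cm, kx in cm^3/d per cm/cm.
eta: 1.002e-9
kx:
  alpha: 0.05
  beta: 2.5
kr:
  - {type: 0, age_min: 0, age_max: .inf, kr: 0.0}
  - {type: 1, age_min: 0, age_max: .inf, kr: 5.0e-6}
  - {type: 2, age_min: 0, age_max: 30, kr: 8.5e-5}
  - {type: 2, age_min: 30, age_max: .inf, kr: 2.0e-5}
  - {type: 3, age_min: 0, age_max: 30, kr: 8.5e-5}
  - {type: 3, age_min: 30, age_max: .inf, kr: 2.0e-5}
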