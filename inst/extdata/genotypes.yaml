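# Growth and tropism parameter presets per grapevine rootstock genotype,
# estimated from 3D-digitized field root systems six months after planting.
# Units: lmax, lb, la, ln, a in cm; r in cm/d; theta in degrees; sigma is
# the SD of random angular change per unit root length; N is the tropism
# strength (candidate directions per growth step); p_gravi the probability
# of gravitropic (vs plagiotropic) behaviour of type-2 roots.
"101-14":
  type2:
    lmax: 99.5
    r: 0.28
    lb: {mean: 8.4, sd: 6.2}
    la: {mean: 11.8, sd: 8.3}
    ln: {mean: 4.1, sd: 3.2}
    theta: {mean: 54.4, sd: 20.6}
    a: {mean: 0.23, sd: 0.04}
    p_gravi: 0.85
    "N": 2
    sigma: 0.2
  type3:
    lmax: 47.2
    r: 0.07
    theta: {mean: 57.6, sd: 21.9}
    a: {mean: 0.05, sd: 0.02}
    "N": 1
    sigma: 0.2
"SO4":
  type2:
    lmax: 89.9
    r: 0.29
    lb: {mean: 7.8, sd: 5.9}
    la: {mean: 16.4, sd: 9.4}
    ln: {mean: 4.8, sd: 3.5}
    theta: {mean: 51.8, sd: 22.5}
    a: {mean: 0.20, sd: 0.04}
    p_gravi: 0.65
    "N": 2
    sigma: 0.2
  type3:
    lmax: 66.7
    r: 0.08
    theta: {mean: 50.4, sd: 22.5}
    a: {mean: 0.05, sd: 0.02}
    "N": 1
    sigma: 0.2
"R110":
  type2:
    lmax: 110.1
    r: 0.37
    lb: {mean: 11.9, sd: 10.6}
    la: {mean: 25.6, sd: 16.9}
    ln: {mean: 6.7, sd: 6.4}
    theta: {mean: 54.9, sd: 23.0}
    a: {mean: 0.22, sd: 0.03}
    p_gravi: 0.95
    "N": 2
    sigma: 0.2
  type3:
    lmax: 77.4
    r: 0.10
    theta: {mean: 51.46, sd: 22.5}
    a: {mean: 0.05, sd: 0.02}
    "N": 1
    sigma: 0.2
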