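# Fitted compaction-model constants, case-study-1 nominal ("no mismatch") set.
xi1: 0.036
xi2: 0.030
rho_b: 0.365      # bulk density, g/cm^3 (used when the glidant density model is inactive)
rho_c: 0.265      # Kawakita critical relative density
kaw_a: 0.80       # Kawakita a (maximum degree of compression)
kaw_inv_b: 10.26  # Kawakita 1/b, MPa
rho_t: 1.53       # true (solid) density, g/cm^3
eps0: 0.08        # in-die elastic recovery at full compaction
rho_c_eps: 0.57   # relative density below which no elastic recovery occurs
sigma0: 11.67     # zero-porosity tensile strength, MPa (sigma_0,phi)
rho_c0: 0.57      # critical tensile density at zero glidant shear
rho_cinf: 0.61    # critical tensile density at infinite glidant shear
b1: 0.31
b2: 0.38
b3: 8.40
rho_b_inf: .na    # glidant bulk-density model inactive for case study 1
rho_b_0: .na
r1: .na
r2: .na
r3: .na
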