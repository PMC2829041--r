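# Base-case parameter set for the leading-edge adhesion/protrusion model.
# Units: rate constants in 1/min, D_r in um^2/min; gains and K's dimensionless.
# k_ecm is the ECM coupling parameter and is the quantity most often varied
# (0.03 / 0.1 / 0.3 1/min span the monostable-low, bistable and
# monostable-high regimes when E_s = I_n = 0).
k_ecm: 0.1
E_s: 0.0
I_n: 0.0
C_s: 10.0
k_d_n: 0.05
p0: 5.0e-3
v0: 1.0e-2
K_v: 0.2
D_r: 15.0
rate_constants:
  s: {k_a: 0.005, k_d: 0.01}
  m: {k_a: 20.0, k_d: 2.0}
  x: {k_a: 15.0, k_d: 5.0}
  r: {k_a: 40.0, k_d: 4.0}
  p: {k_a: 18.0, k_d: 4.0}
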