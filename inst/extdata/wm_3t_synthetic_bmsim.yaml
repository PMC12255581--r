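# Synthetic white-matter-like multi-pool environment (4 CEST pools + 1 NOE
# pool + semisolid MT). Pool values are illustrative defaults assembled from
# typical in vivo ranges, NOT a published parameter set; useful for
# exercising generic multi-pool yaml loading and simulation.
water_pool:
  f: 1
  t1: 1.05
  t2: 0.04
cest_pool:
  amide:
    f: 0.00064864864864864873
    t1: 1.05
    t2: 0.1
    k: 30
    dw: 3.5
  guanidine:
    f: 0.00050450450450450455
    t1: 1.05
    t2: 0.17
    k: 1100
    dw: 2
  amine:
    f: 6.4864864864864868e-05
    t1: 1.05
    t2: 0.2
    k: 5500
    dw: 3
  hydroxyl:
    f: 3.2432432432432434e-05
    t1: 1.05
    t2: 0.1
    k: 3500
    dw: 1.3
  noe:
    f: 0.0016216216216216217
    t1: 1.05
    t2: 0.005
    k: 16
    dw: -3.5
mt_pool:
  f: 0.139
  t1: 1.05
  t2: 9.0999999999999999e-06
  k: 40
  dw: -2.5
  lineshape: lorentzian
b0: 3
gamma: 42.5764
rel_b1: 1
db0: 0
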