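# Default misspecification grid for the selection-model coefficients.
# Additive shifts on the log (linear-predictor) scale at three levels:
# 50% (mild), 100% (evidence-suggested), 200% (extreme). Where `companion`
# is true, the shift is applied alongside a -0.15 shift of the death main
# effect (lg1) so that died-stratum probabilities have headroom to rise
# without leaving (0, 1]. Unknown-ethnicity coefficients are never shifted.
companion:
  lg1: -0.15
eq1:
  - target: lg0
    deltas: {"50": -0.05, "100": -0.1, "200": -0.2}
    companion: false
  - target: lg1
    deltas: {"50": -0.075, "100": -0.15, "200": -0.3}
    companion: false
  - target: la_Black
    deltas: {"50": 0.125, "100": 0.25, "200": 0.5}
    companion: true
  - target: la_Asian
    deltas: {"50": 0.125, "100": 0.25, "200": 0.5}
    companion: true
  - target: la_Mixed/Other
    deltas: {"50": 0.1, "100": 0.2, "200": 0.4}
    companion: true
  - target: lb_Black
    deltas: {"50": -0.1, "100": -0.2, "200": -0.4}
    companion: false
  - target: lb_Asian
    deltas: {"50": -0.1, "100": -0.2, "200": -0.4}
    companion: false
  - target: lb_Mixed/Other
    deltas: {"50": -0.1, "100": -0.2, "200": -0.4}
    companion: false
eq2:
  - target: lg2
    deltas: {"50": 0.25, "100": 0.5, "200": 1.0}
    companion: true
  - target: lg3
    deltas: {"50": -0.35, "100": -0.7, "200": -1.4}
    companion: false
  - target: lc_Black
    deltas: {"50": 0.125, "100": 0.25, "200": 0.5}
    companion: true
  - target: lc_Asian
    deltas: {"50": -0.1, "100": -0.2, "200": -0.4}
    companion: true
  - target: lc_Mixed/Other
    deltas: {"50": 0.125, "100": 0.25, "200": 0.5}
    companion: true
  - target: ld_Black
    deltas: {"50": 0.1, "100": 0.2, "200": 0.4}
    companion: true
  - target: ld_Asian
    deltas: {"50": 0.1, "100": 0.2, "200": 0.4}
    companion: true
  - target: ld_Mixed/Other
    deltas: {"50": 0.1, "100": 0.2, "200": 0.4}
    companion: true
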