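# Reconstructed three-toxicity weight matrix (renal, neurological,
# hematological) with nu = 2.5 and elicited normalized target 0.28.
toxicities:
- name: renal
  weights: [0.0, 0.5, 0.75, 1.0, 1.5]
  dlt: [no, no, no, yes, yes]
- name: neurological
  weights: [0.0, 0.5, 0.75, 1.0, 1.5]
  dlt: [no, no, no, yes, yes]
- name: hematological
  weights: [0.0, 0.0, 0.5, 0.75, 1.0]
  dlt: [no, no, no, no, yes]
nu: 2.5
theta_star: 0.28
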