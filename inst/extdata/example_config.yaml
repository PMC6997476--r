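# example run: butanol-like model chain on the bundled analytic surface
zmatrix: butanol_chain.zmat
torsion_prefix: PHI
has_sym_plane: true
d: 30
eps_red: 3
eps_freq: 5
k_bond: 1.3
seed: 1
batches:
  - cycles: 50
    d: 30
temperatures: [300, 1000, 2500]
lambda_zpe: 0.951
outdir: torsconf_out
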