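{
  "_comment": "Synthetic ground-truth parameterization for model variant B (neck-swinging mechanism, negative feedback). Fixture values; see ground_truth_A.json for unit conventions. k_phos_free has units 1/(molecule h).",
  "vmax1": 9.2e6,
  "K1E": 5e5,
  "K1S": 2e6,
  "kdp_PI4K": 2.0,
  "vmax3": 7.2e6,
  "K3E": 5e5,
  "K3S": 5e5,
  "k9": 2.0,
  "vmax5": 4.3e5,
  "K5E": 2e4,
  "K5S": 1e6,
  "k10": 1.0,
  "k_act": 0.2,
  "vmax_cer": 1e4,
  "K_cer": 1e6,
  "k_pdbu": 2.0,
  "k_deact": 2.0,
  "s_PKD": 2.5e4,
  "s_PI4K": 1e5,
  "s_CERT": 2.5e4,
  "s_ect_PI4K": 2e6,
  "s_ect_CERT": 5e6,
  "d_PKD": 0.05,
  "d_PI4K": 0.05,
  "d_CERT": 0.05,
  "k_inh": 10.0,
  "k_phos_free": 1.27e-9
}
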