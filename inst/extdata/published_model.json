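{
  "variables": ["T2_NCRNET_z.perc", "T2_NCRNET_zs.var", "T1Gd_NCRNET_zsnu"],
  "coefficients": [13.693, -0.41, 31.842],
  "intercept": -19.5,
  "w": null,
  "combination": "T1Gd_NCRNET+T2_NCRNET",
  "targets": {"LGG": -10, "HGG": 10}
}
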