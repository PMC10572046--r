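{"a_x":1,"a_y":1.5,"K_x":31490.9769822284,"K_y":31490.9769822284,"alpha":50,"epsilon":1,"beta_x":0.0022947072516353,"beta_y":0.0022947072516353,"p_x":0.995,"p_y":0.995,"d_x":1,"d_y":1,"r_x":0.458941450327061,"r_y":0.458941450327061,"kind":"full"}
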