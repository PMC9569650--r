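basin,phi_center_deg,psi_center_deg,phi_sd_deg,psi_sd_deg
helix,-63,-42,10,10
strand,-135,135,10,10
coil,-70,150,15,15
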