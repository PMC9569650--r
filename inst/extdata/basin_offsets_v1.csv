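atom_name,helix,strand,coil
CA,2.6,-1.4,0
CB,-0.4,1.2,0
HA,-0.35,0.4,0
H,-0.2,0.3,0
N,-1.2,1.5,0
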