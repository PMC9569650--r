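id,A_hz,B_hz,C_hz,theta0_deg
bax1997,7.09,-1.42,1.55,-60
bax1993,6.51,-1.76,1.60,-60
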