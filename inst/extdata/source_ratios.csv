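stage,time_hr,ratio_dorsal_length,ratio_posterior_width,ratio_anterior_width
S7,3,0.5,0.5,0.5
S8E,7.5,0.5,0.5,0.5
S8L,10.5,0.5,0.5,0.5
S9E,13.5,0.5,0.5,0.5
S9L,16.5,0.5,0.5,0.5
S10A,19.5,0.5,0.5,0.5
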