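subject,tau_stim_s,tau_rec_s
1,9.63,6.46
2,46.17,5.22
3,34.56,4.30
4,14.22,3.38
5,34.65,7.88
6,12.46,4.36
7,11.76,5.61
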