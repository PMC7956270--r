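# Coherent neutron scattering lengths, Sears tabulation, in femtometres.
isotope,b_coh_fm
H,-3.7390
D,6.671
C,6.6460
O,5.803
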