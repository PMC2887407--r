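(outgroup:0.5,(((((((g1_sp1:0.0175,g1_sp2:0.0175):0.0175,g1_sp3:0.035):0.0175,g1_sp4:0.0525):0.0175,g1_sp5:0.07):0.0175,g1_sp6:0.0875):0.0175,g1_sp7:0.105):0.18,(((((g5_sp1:0.021,g5_sp2:0.021):0.021,g5_sp3:0.042):0.021,g5_sp4:0.063):0.021,g5_sp5:0.084):0.021,g5_sp6:0.105):0.18):0.215);
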