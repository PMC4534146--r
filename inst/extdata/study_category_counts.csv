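category,all,dcis_only,dcis_ibc
unable_to_determine,112,49,63
no_gains,43,29,14
only_1q,31,15,16
only_8q24,19,8,11
only_11q13,8,4,4
two_of_three,45,12,33
all_three,22,5,17
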