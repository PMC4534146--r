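marker,all_cases,ibc,dcis_only,tp,fn,fp,tn
1q,200,113,87,66,47,38,49
8q24,217,122,95,64,58,32,63
11q13,206,116,90,44,72,19,71
HER2,280,158,122,54,104,38,84
1q+8q24,186,107,79,37,70,16,63
1q+11q13,172,96,76,25,71,9,67
1q+HER2,200,113,87,34,79,21,66
8q24+11q13,193,108,85,27,81,7,78
8q24+HER2,217,122,95,33,89,21,74
11q13+HER2,206,116,90,29,87,12,78
1q+8q24+11q13,168,95,73,17,78,5,68
all_four,168,95,73,15,80,5,68
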