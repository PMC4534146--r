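marker,status,all,dcis_only,dcis_ibc
1q,no_signal,80,35,45
1q,no,96,49,47
1q,yes,104,38,66
8q24,no_signal,63,27,36
8q24,no,121,63,58
8q24,yes,96,32,64
11q13,no_signal,74,32,42
11q13,no,143,71,72
11q13,yes,63,19,44
HER2,no,188,84,104
HER2,yes,92,38,54
1q+8q24,no_signal,94,43,51
1q+8q24,no,133,63,70
1q+8q24,yes,53,16,37
1q+11q13,no_signal,108,46,62
1q+11q13,no,138,67,71
1q+11q13,yes,34,9,25
1q+HER2,no_signal,80,35,45
1q+HER2,no,145,66,79
1q+HER2,yes,55,21,34
8q24+11q13,no_signal,87,37,50
8q24+11q13,no,159,78,81
8q24+11q13,yes,34,7,27
8q24+HER2,no_signal,63,27,36
8q24+HER2,no,163,74,89
8q24+HER2,yes,54,21,33
11q13+HER2,no_signal,74,32,42
11q13+HER2,no,165,78,87
11q13+HER2,yes,41,12,29
1q+8q24+11q13,no_signal,112,49,63
1q+8q24+11q13,no,146,68,78
1q+8q24+11q13,yes,22,5,17
1q+8q24+HER2,no_signal,94,43,51
1q+8q24+HER2,no,150,66,84
1q+8q24+HER2,yes,36,13,23
1q+11q13+HER2,no_signal,105,44,61
1q+11q13+HER2,no,140,68,72
1q+11q13+HER2,yes,35,10,25
8q24+11q13+HER2,no_signal,113,44,69
8q24+11q13+HER2,no,167,78,89
all_four,no_signal,112,49,63
all_four,no,148,68,80
all_four,yes,20,5,15
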