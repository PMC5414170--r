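time_days,r_t1_mm,r_t2_mm
0,9.19528104378295,10
30,19.0952810437829,19.9
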