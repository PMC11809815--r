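group,animal_id,nt,wt,pat,pplo
control,c1,1688,276,109,0.62
control,c2,1400,254,121,0.53
control,c3,1290,288,98,0.41
SUB,s1,677,277,100,0.32
SUB,s2,983,258,119,0.38
SUB,s3,832,295,101,0.35
SUB+BM86,m1,1285,243,76,0.61
SUB+BM86,m2,1433,255,98,0.56
SUB+BM86,m3,1045,224,100,0.58
BM86,b1,704,234,92,0.32
BM86,b2,900,198,88,0.39
BM86,b3,613,222,113,0.34
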