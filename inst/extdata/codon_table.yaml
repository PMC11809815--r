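UGC:
  tokens:
  - B
  durations:
  - 3.0
  n_base: 1.0
CAA:
  tokens:
  - E
  - F
  durations:
  - 2.0
  - 1.0
  n_base: 2.0
UCG:
  tokens:
  - G
  - D
  durations:
  - 2.0
  - 1.0
  n_base: 1.0
UCC:
  tokens:
  - G
  - E
  - D
  durations:
  - 2.0
  - 0.5
  - 0.5
  n_base: 1.0
GCG:
  tokens:
  - C
  - D
  - D
  durations:
  - 1.5
  - 0.5
  - 1.0
  n_base: 2.0
GCC:
  tokens:
  - C
  - D
  - E
  - D
  durations:
  - 1.5
  - 0.5
  - 0.5
  - 0.5
  n_base: 2.0
GGA:
  tokens:
  - G
  - A
  durations:
  - 2.0
  - 1.0
  n_base: 2.0
GGC:
  tokens:
  - G
  - A
  - D
  - D
  durations:
  - 1.5
  - 0.5
  - 0.5
  - 0.5
  n_base: 2.0
UCA:
  tokens:
  - G
  durations:
  - 3.0
  n_base: 1.0
UCU:
  tokens:
  - G
  - A
  durations:
  - 1.5
  - 1.5
  n_base: 1.0
UUU:
  tokens:
  - G
  - B
  durations:
  - 1.5
  - 1.5
  n_base: 1.0
UUC:
  tokens:
  - G
  - A
  - B
  durations:
  - 2.0
  - 0.5
  - 0.5
  n_base: 1.0
UUA:
  tokens:
  - E
  durations:
  - 3.0
  n_base: 1.0
UUG:
  tokens:
  - E
  - F
  durations:
  - 2.0
  - 1.0
  n_base: 1.0
UAU:
  tokens:
  - A
  - C
  durations:
  - 1.5
  - 1.5
  n_base: 1.0
UAC:
  tokens:
  - A
  - B
  - C
  durations:
  - 2.0
  - 0.5
  - 0.5
  n_base: 1.0
UAA:
  tokens:
  - z
  durations:
  - 3.0
  n_base: 1.0
UAG:
  tokens:
  - z
  durations:
  - 3.0
  n_base: 1.0
UGU:
  tokens:
  - D
  - F
  durations:
  - 1.5
  - 1.5
  n_base: 1.0
UGA:
  tokens:
  - z
  durations:
  - 3.0
  n_base: 1.0
UGG:
  tokens:
  - G
  - A
  durations:
  - 2.0
  - 1.0
  n_base: 1.0
CUU:
  tokens:
  - E
  - G
  durations:
  - 1.5
  - 1.5
  n_base: 1.0
CUC:
  tokens:
  - E
  - F
  - G
  durations:
  - 2.0
  - 0.5
  - 0.5
  n_base: 1.0
CUA:
  tokens:
  - E
  durations:
  - 3.0
  n_base: 1.0
CUG:
  tokens:
  - E
  - F
  durations:
  - 2.0
  - 1.0
  n_base: 1.0
CCU:
  tokens:
  - A
  - C
  durations:
  - 1.5
  - 1.5
  n_base: 1.0
CCC:
  tokens:
  - A
  - B
  - C
  durations:
  - 2.0
  - 0.5
  - 0.5
  n_base: 1.0
CCA:
  tokens:
  - A
  durations:
  - 3.0
  n_base: 1.0
CCG:
  tokens:
  - A
  - B
  durations:
  - 2.0
  - 1.0
  n_base: 1.0
CAU:
  tokens:
  - B
  - D
  durations:
  - 1.5
  - 1.5
  n_base: 1.0
CAC:
  tokens:
  - B
  - C
  - D
  durations:
  - 2.0
  - 0.5
  - 0.5
  n_base: 1.0
CAG:
  tokens:
  - B
  - C
  durations:
  - 2.0
  - 1.0
  n_base: 1.0
CGU:
  tokens:
  - C
  - E
  durations:
  - 1.5
  - 1.5
  n_base: 1.0
CGC:
  tokens:
  - C
  - D
  - E
  durations:
  - 2.0
  - 0.5
  - 0.5
  n_base: 1.0
CGA:
  tokens:
  - C
  durations:
  - 3.0
  n_base: 1.0
CGG:
  tokens:
  - C
  - D
  durations:
  - 2.0
  - 1.0
  n_base: 1.0
AUU:
  tokens:
  - C
  - E
  durations:
  - 1.5
  - 1.5
  n_base: 1.0
AUC:
  tokens:
  - C
  - D
  - E
  durations:
  - 2.0
  - 0.5
  - 0.5
  n_base: 1.0
AUA:
  tokens:
  - C
  durations:
  - 3.0
  n_base: 1.0
AUG:
  tokens:
  - F
  - G
  durations:
  - 2.0
  - 1.0
  n_base: 1.0
ACU:
  tokens:
  - E
  - G
  durations:
  - 1.5
  - 1.5
  n_base: 1.0
ACC:
  tokens:
  - E
  - F
  - G
  durations:
  - 2.0
  - 0.5
  - 0.5
  n_base: 1.0
ACA:
  tokens:
  - E
  durations:
  - 3.0
  n_base: 1.0
ACG:
  tokens:
  - E
  - F
  durations:
  - 2.0
  - 1.0
  n_base: 1.0
AAU:
  tokens:
  - G
  - B
  durations:
  - 1.5
  - 1.5
  n_base: 1.0
AAC:
  tokens:
  - G
  - A
  - B
  durations:
  - 2.0
  - 0.5
  - 0.5
  n_base: 1.0
AAA:
  tokens:
  - D
  durations:
  - 3.0
  n_base: 1.0
AAG:
  tokens:
  - D
  - E
  durations:
  - 2.0
  - 1.0
  n_base: 1.0
AGU:
  tokens:
  - D
  - F
  durations:
  - 1.5
  - 1.5
  n_base: 1.0
AGC:
  tokens:
  - D
  - E
  - F
  durations:
  - 2.0
  - 0.5
  - 0.5
  n_base: 1.0
AGA:
  tokens:
  - C
  durations:
  - 3.0
  n_base: 1.0
AGG:
  tokens:
  - C
  - D
  durations:
  - 2.0
  - 1.0
  n_base: 1.0
GUU:
  tokens:
  - F
  - A
  durations:
  - 1.5
  - 1.5
  n_base: 1.0
GUC:
  tokens:
  - F
  - G
  - A
  durations:
  - 2.0
  - 0.5
  - 0.5
  n_base: 1.0
GUA:
  tokens:
  - F
  durations:
  - 3.0
  n_base: 1.0
GUG:
  tokens:
  - F
  - G
  durations:
  - 2.0
  - 1.0
  n_base: 1.0
GCU:
  tokens:
  - C
  - E
  durations:
  - 1.5
  - 1.5
  n_base: 1.0
GCA:
  tokens:
  - C
  durations:
  - 3.0
  n_base: 1.0
GAU:
  tokens:
  - E
  - G
  durations:
  - 1.5
  - 1.5
  n_base: 1.0
GAC:
  tokens:
  - E
  - F
  - G
  durations:
  - 2.0
  - 0.5
  - 0.5
  n_base: 1.0
GAA:
  tokens:
  - F
  durations:
  - 3.0
  n_base: 1.0
GAG:
  tokens:
  - F
  - G
  durations:
  - 2.0
  - 1.0
  n_base: 1.0
GGU:
  tokens:
  - A
  - C
  durations:
  - 1.5
  - 1.5
  n_base: 1.0
GGG:
  tokens:
  - A
  - B
  durations:
  - 2.0
  - 1.0
  n_base: 1.0
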