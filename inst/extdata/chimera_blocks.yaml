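# Ordered epitope blocks of the Q38-95 chimeric antigen. Blocks are
# joined with lowercase GGGS linkers by assemble_chimera().
- name: Q38_part1
  sequence: MACATLKRTHDWDPLHSPNGRSPKPSPFGEVPPKSSPLESGSPSATPPASPTGLSPGGLLSPVRRDQPLFTFRQVGLICERMMKERESQIRDEYDHVLSAKLAEQYDTFVKFTYDQIQKRFEGATPSYLS
- name: Q38_part2
  sequence: HKPFGSPSSPSSSAIAAAAAAAKRPSPFAEAVCPKQLTFNTGSRPDSPPSMVLFTFKQALREQYDAVLTNKLAEQYDAAAPSYLS
- name: BM95_epitope
  sequence: RVQKGTVLCECPWNQHLVGDTCISDCVDKKCHE
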