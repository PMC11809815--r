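[
  {"model_id": "silico-1", "protein_id": "SUB", "intervals": [[138, 146]]},
  {"model_id": "silico-2", "protein_id": "SUB", "intervals": [[138, 146]]},
  {"model_id": "music", "protein_id": "SUB", "intervals": [[138, 146]]},
  {"model_id": "silico-1", "protein_id": "BM95", "intervals": [[268, 307]]},
  {"model_id": "silico-2", "protein_id": "BM95", "intervals": [[249, 288]]},
  {"model_id": "music", "protein_id": "BM95", "intervals": [[268, 307]]}
]
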