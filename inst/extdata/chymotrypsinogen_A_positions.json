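{
  "id": "CTRA_BOVIN",
  "numbering": "chymotrypsinogen",
  "pocket": { "res189": 189, "res216": 216, "res226": 226 },
  "catalytic": { "his": 57, "asp": 102, "ser": 195 },
  "activation": { "p1": 15, "motif_start": 16 }
}
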