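{
  "schema_version": "1.0",
  "comment": "Predicted lipopeptides whose lengths do not match any family template; each records the family template it is thought to derive from. Excluded from classification references by default.",
  "predicted": [
    {"name": "LP4",   "derived_from": "Thanafactin", "mechanism": "deletion",    "sequence": ["Val","Leu","Ser","Ile"]},
    {"name": "LP7",   "derived_from": "Bananamide",  "mechanism": "duplication", "sequence": ["Leu","Glu","Thr","Leu","Ser","Leu","Ile"]},
    {"name": "LP9",   "derived_from": "Putisolvin",  "mechanism": "deletion",    "sequence": ["Leu","Glu","Leu","Leu","Gln","Ser","Leu","Val","Ser"]},
    {"name": "LP10a", "derived_from": "Bananamide",  "mechanism": "addition",    "sequence": ["Leu","Glu","Thr","Ile","Leu","Ser","Leu","Gln","Ile","Glu"]},
    {"name": "LP10b", "derived_from": "Xantholysin", "mechanism": "deletion",    "sequence": ["Leu","Glu","Gln","Val","Leu","Gln","Val","Leu","Gln","Ile"]},
    {"name": "LP12",  "derived_from": "Bananamide",  "mechanism": "addition",    "sequence": ["Leu","Glu","Thr","Ile","Leu","Ser","Leu","Ser","Leu","Gln","Ile","Glu"]}
  ]
}
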