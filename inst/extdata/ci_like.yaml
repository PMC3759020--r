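# Cochlear-implant-like group: reduced lexicon coverage, shorter retrieval.
# Calibrated so 27 subjects produce on the order of 105 distinct words.
label: CI
n_subjects: 27
zipf_exponent: 1.5
retrieval_mean: 10
retrieval_sd: 3
p_switch: 0.35
p_know: 0.75
know_decay: 0.8
subcategories:
  pets: 15
  farm: 18
  african: 22
  birds: 21
  fish: 18
  insects: 16
  reptiles: 14
  rodents: 10
  forest: 16
  ocean: 20
  exotic: 12
  arctic: 12
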