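"file","md5"
"screening_compounds.csv","f7258ee253bf23afb981cab4e0b5d5a8"
"screening_effects.csv","c1ba4a901e80fdf33fd6026a041bdfa1"
"screening_opinions.csv","d56c9c51d9245799ee251a9dc2d4f60e"
"screening_studies.csv","d03151fd00b1e9a9a07da550866047a8"
"corpus_categories.csv","7f10c5c537ee019169d72da3b8b4e6ea"
"mini_ontology.ttl","1136d7db1e7555bcdcb75747488e9ab7"
"effect_token_alignment.csv","86a140243ddff4f856ec1a1b1d488054"
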