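"opinion_id","year","compound_id","is_placeholder"
"OP-1-2-4-trihydroxybenzene",2015,"1-2-4-trihydroxybenzene",TRUE
"OP-1-hexyl-4-5-diamino-pyrazole-sulfate",2015,"1-hexyl-4-5-diamino-pyrazole-sulfate",TRUE
"OP-2-6-diamino-3-pyridin-3-yl-azo-pyridine",2015,"2-6-diamino-3-pyridin-3-yl-azo-pyridine",TRUE
"OP-2-6-dihydroxyethylaminotoluene",2015,"2-6-dihydroxyethylaminotoluene",TRUE
"OP-2-7-naphthalenediol",2015,"2-7-naphthalenediol",TRUE
"OP-2-amino-4-hydroxyethylaminoanisole-sulfate",2015,"2-amino-4-hydroxyethylaminoanisole-sulfate",TRUE
"OP-2-amino-5-ethylphenol-hcl",2015,"2-amino-5-ethylphenol-hcl",TRUE
"OP-2-hydroxyethylamino-5-nitroanisole",2015,"2-hydroxyethylamino-5-nitroanisole",TRUE
"OP-5-amino-6-chloro-o-cresol",2015,"5-amino-6-chloro-o-cresol",TRUE
"OP-acetylated-vetiver-oil-avo-vetiveryl-acetate",2015,"acetylated-vetiver-oil-avo-vetiveryl-acetate",TRUE
"OP-acid-black-1",2015,"acid-black-1",TRUE
"OP-acid-orange-7",2015,"acid-orange-7",TRUE
"OP-acid-red-92",2015,"acid-red-92",TRUE
"OP-basic-brown-17",2015,"basic-brown-17",TRUE
"OP-basic-orange-31",2015,"basic-orange-31",TRUE
"OP-basic-red-51",2015,"basic-red-51",TRUE
"OP-basic-red-76",2015,"basic-red-76",TRUE
"OP-basic-violet-2",2015,"basic-violet-2",TRUE
"OP-basic-yellow-57",2015,"basic-yellow-57",TRUE
"OP-basic-yellow-87",2015,"basic-yellow-87",TRUE
"OP-bis-butylbenzoate-diaminotriazine-aminopropyltrisiloxane",2015,"bis-butylbenzoate-diaminotriazine-aminopropyltrisiloxane",TRUE
"OP-butylphenyl-methylpropional",2015,"butylphenyl-methylpropional",TRUE
"OP-cetylpyridinium-chloride",2015,"cetylpyridinium-chloride",TRUE
"OP-citric-acid-and-silver-citrate",2015,"citric-acid-and-silver-citrate",TRUE
"OP-decamethylcyclopentasiloxane-cyclopentasiloxane-d5",2015,"decamethylcyclopentasiloxane-cyclopentasiloxane-d5",TRUE
"OP-diethylene-glycol-monoethyl-ether",2015,"diethylene-glycol-monoethyl-ether",TRUE
"OP-disperse-black-9",2015,"disperse-black-9",TRUE
"OP-disperse-blue-377",2015,"disperse-blue-377",TRUE
"OP-disperse-violet-1",2015,"disperse-violet-1",TRUE
"OP-ecog",2015,"ecog",TRUE
"OP-hc-blue-no-14",2015,"hc-blue-no-14",TRUE
"OP-hc-blue-no-15",2015,"hc-blue-no-15",TRUE
"OP-hc-orange-no-6",2015,"hc-orange-no-6",TRUE
"OP-hc-red-no-13",2015,"hc-red-no-13",TRUE
"OP-hc-red-no-7",2015,"hc-red-no-7",TRUE
"OP-hc-yellow-no-13",2015,"hc-yellow-no-13",TRUE
"OP-hc-yellow-no-9",2015,"hc-yellow-no-9",TRUE
"OP-hydroxyethyl-2-nitro-p-toluidine",2015,"hydroxyethyl-2-nitro-p-toluidine",TRUE
"OP-hydroxyethyl-3-4-methylenedioxyaniline-hcl",2015,"hydroxyethyl-3-4-methylenedioxyaniline-hcl",TRUE
"OP-hydroxyethyl-p-phenylenediamine-sulfate",2015,"hydroxyethyl-p-phenylenediamine-sulfate",TRUE
"OP-hydroxypropyl-p-phenylenediamine-and-its-dihydrochloride-salt-a165",2015,"hydroxypropyl-p-phenylenediamine-and-its-dihydrochloride-salt-a165",TRUE
"OP-methoxypropylamino-cyclohexenylidene-ethoxyethylcyanoacetate-s87",2015,"methoxypropylamino-cyclohexenylidene-ethoxyethylcyanoacetate-s87",TRUE
"OP-methylimidazoliumpropyl-p-phenylenediamine-hcl-a166",2015,"methylimidazoliumpropyl-p-phenylenediamine-hcl-a166",TRUE
"OP-n-methyl-2-pyrrolidone",2015,"n-methyl-2-pyrrolidone",TRUE
"OP-n-n-bis-2-hydroxyethyl-2-nitro-p-phenylenediamine",2015,"n-n-bis-2-hydroxyethyl-2-nitro-p-phenylenediamine",TRUE
"OP-o-aminophenol",2015,"o-aminophenol",TRUE
"OP-o-phenylphenol-sodium-o-phenylphenate-and-potassium-o-phenylphenate",2015,"o-phenylphenol-sodium-o-phenylphenate-and-potassium-o-phenylphenate",TRUE
"OP-phenoxyethanol",2015,"phenoxyethanol",TRUE
"OP-polysilicone-15",2015,"polysilicone-15",TRUE
"OP-toluene-2-5-diamine-and-its-sulfate-colipa-no-a5",2015,"toluene-2-5-diamine-and-its-sulfate-colipa-no-a5",TRUE
"OP-triclosan",2015,"triclosan",TRUE
"OP-vitamin-a",2015,"vitamin-a",TRUE
"OP-zinc-pyrithione",2015,"zinc-pyrithione",TRUE
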