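"compound_id","ingredient_name","inci_name","cas_number","ec_number","smiles","use_category","is_polymer","is_placeholder"
"1-2-4-trihydroxybenzene","1,2,4-Trihydroxybenzene","","","","","hair dye",FALSE,FALSE
"1-hexyl-4-5-diamino-pyrazole-sulfate","1-Hexyl 4,5-diamino pyrazole sulfate","","","","","hair dye",FALSE,FALSE
"2-6-diamino-3-pyridin-3-yl-azo-pyridine","2,6-Diamino-3-((pyridin-3-yl)azo)pyridine","","","","","hair dye",FALSE,FALSE
"2-6-dihydroxyethylaminotoluene","2,6-Dihydroxyethylaminotoluene","","","","","hair dye",FALSE,FALSE
"2-7-naphthalenediol","2,7-Naphthalenediol","","","","","hair dye",FALSE,FALSE
"2-amino-4-hydroxyethylaminoanisole-sulfate","2-Amino-4-hydroxyethylaminoanisole sulfate","","","","","hair dye",FALSE,FALSE
"2-amino-5-ethylphenol-hcl","2-Amino-5-ethylphenol HCl","","","","","hair dye",FALSE,FALSE
"2-hydroxyethylamino-5-nitroanisole","2-Hydroxyethylamino-5-nitroanisole","","","","","hair dye",FALSE,FALSE
"5-amino-6-chloro-o-cresol","5-Amino-6-chloro-o-cresol","","","","","hair dye",FALSE,FALSE
"acetylated-vetiver-oil-avo-vetiveryl-acetate","Acetylated vetiver oil—AVO = vetiveryl acetate","","","","","fragrance",FALSE,FALSE
"acid-black-1","Acid black 1","","","","","hair dye",FALSE,FALSE
"acid-orange-7","Acid orange 7","","","","","hair dye",FALSE,FALSE
"acid-red-92","Acid red 92","","","","","hair dye",FALSE,FALSE
"basic-brown-17","Basic Brown 17","","","","","hair dye",FALSE,FALSE
"basic-orange-31","Basic orange 31","","","","","hair dye",FALSE,FALSE
"basic-red-51","Basic Red 51","","","","","hair dye",FALSE,FALSE
"basic-red-76","Basic red 76","","","","","hair dye",FALSE,FALSE
"basic-violet-2","Basic violet 2","","","","","hair dye",FALSE,FALSE
"basic-yellow-57","Basic yellow 57","","68391-31-1","","","hair dye",FALSE,FALSE
"basic-yellow-87","Basic yellow 87","","","","","hair dye",FALSE,FALSE
"bis-butylbenzoate-diaminotriazine-aminopropyltrisiloxane","Bis(butylbenzoate) diaminotriazine aminopropyltrisiloxane","","","","","UV filter",FALSE,FALSE
"butylphenyl-methylpropional","Butylphenyl methylpropional","","","","","fragrance",FALSE,FALSE
"cetylpyridinium-chloride","Cetylpyridinium chloride","","","","","preservative/disinfectant",FALSE,FALSE
"citric-acid-and-silver-citrate","Citric acid (and) silver citrate","","","","","preservative/disinfectant",FALSE,FALSE
"decamethylcyclopentasiloxane-cyclopentasiloxane-d5","Decamethylcyclopentasiloxane (cyclopentasiloxane, D5)","","","","","multiple",FALSE,FALSE
"diethylene-glycol-monoethyl-ether","Diethylene glycol monoethyl ether","","","","","solvent",FALSE,FALSE
"disperse-black-9","Disperse black 9","","","","","hair dye",FALSE,FALSE
"disperse-blue-377","Disperse blue 377","","","","","hair dye",FALSE,FALSE
"disperse-violet-1","Disperse violet 1","","","","","hair dye",FALSE,FALSE
"ecog","ecoG+","","","","","preservative/disinfectant",FALSE,FALSE
"hc-blue-no-14","HC blue No. 14","","","","","hair dye",FALSE,FALSE
"hc-blue-no-15","HC blue No. 15","","","","","hair dye",FALSE,FALSE
"hc-orange-no-6","HC orange No. 6","","","","","hair dye",FALSE,FALSE
"hc-red-no-13","HC red No.13","","","","","hair dye",FALSE,FALSE
"hc-red-no-7","HC red No. 7","","","","","hair dye",FALSE,FALSE
"hc-yellow-no-13","HC yellow No. 13","","","","","hair dye",FALSE,FALSE
"hc-yellow-no-9","HC yellow No. 9","","","","","hair dye",FALSE,FALSE
"hydroxyethyl-2-nitro-p-toluidine","Hydroxyethyl-2-nitro-p-toluidine","","","","","hair dye",FALSE,FALSE
"hydroxyethyl-3-4-methylenedioxyaniline-hcl","Hydroxyethyl-3,4-methylenedioxyaniline HCl","","","","","hair dye",FALSE,FALSE
"hydroxyethyl-p-phenylenediamine-sulfate","Hydroxyethyl-p-phenylenediamine sulfate","","","","","hair dye",FALSE,FALSE
"hydroxypropyl-p-phenylenediamine-and-its-dihydrochloride-salt-a165","Hydroxypropyl p-phenylenediamine and its dihydrochloride salt (A165)","","","","","hair dye",FALSE,FALSE
"methoxypropylamino-cyclohexenylidene-ethoxyethylcyanoacetate-s87","Methoxypropylamino cyclohexenylidene ethoxyethylcyanoacetate (S87)","","","","","UV filter",FALSE,FALSE
"methylimidazoliumpropyl-p-phenylenediamine-hcl-a166","Methylimidazoliumpropyl p-phenylenediamine HCl (A166)","","","","","hair dye",FALSE,FALSE
"n-methyl-2-pyrrolidone","N-Methyl-2-pyrrolidone","","872-50-4","","CN1CCCC1=O","solvent",FALSE,FALSE
"n-n-bis-2-hydroxyethyl-2-nitro-p-phenylenediamine","N,N'-Bis-(2-hydroxyethyl)-2-nitro-p-phenylenediamine","","","","","hair dye",FALSE,FALSE
"o-aminophenol","o-Aminophenol","","","","","hair dye",FALSE,FALSE
"o-phenylphenol-sodium-o-phenylphenate-and-potassium-o-phenylphenate","o-Phenylphenol, sodium o-phenylphenate, and potassium o-phenylphenate","","","","","preservative/disinfectant",FALSE,FALSE
"phenoxyethanol","Phenoxyethanol","","122-99-6","","OCCOc1ccccc1","preservative/disinfectant",FALSE,FALSE
"polysilicone-15","Polysilicone-15","","","","","UV filter",TRUE,FALSE
"toluene-2-5-diamine-and-its-sulfate-colipa-no-a5","Toluene-2,5-diamine and its sulfate (COLIPA No. A5)","","","","","hair dye",FALSE,FALSE
"triclosan","Triclosan","","3380-34-5","","Oc1cc(Cl)ccc1Oc1ccc(Cl)cc1Cl","preservative/disinfectant",FALSE,FALSE
"vitamin-a","Vitamin a","","","","","other",FALSE,FALSE
"zinc-pyrithione","Zinc pyrithione","","","","","preservative/disinfectant",FALSE,FALSE
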