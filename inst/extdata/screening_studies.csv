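study_id,compound_id,opinion_id,guideline_id,fields,sccs_comments,study_year,glp_status,ref_in_dossier,additional_information,own_comments,control_recovery_group
basic-red-51-rdt-1,basic-red-51,OP-basic-red-51,OECD_408,"Test animal/species=rat|Test animal/strain=Wistar|Test animal/sex=male and female|Test animal/age value=6|Test animal/age unit=weeks|Test animal/housing conditions=group housed|Test animal/feeding conditions=standard diet ad libitum|Test method/Test substance/identification=Basic Red 51|Test method/Test substance/purity=97%|Test method/Test substance/source or origin=industry dossier|Test method/Test substance/physicochemical properties=solid; water-soluble|Test method/Test substance/homogeneity and stability=YES|Test method/Test condition/Oral administration/route=gavage|Test method/Test condition/dose levels=0; 50; 150; 450|Test method/Test condition/animals per group=10|Test method/Test condition/dose-volume ml\/kg bw=10|Clinical biochemistry/Hepatocellular effect/alp=increased|Clinical biochemistry/Hepatocellular effect/ggt=increased|Pathology/Histopathology/hepatic necrosis=YES|Results/endpoints and methods=clinical biochemistry and histopathology|Results/results description=described for all endpoints|Results/statistical methods=ANOVA with Dunnett post hoc|Results/quantitative results reliability=consistent across dose groups",no major deviations noted,2013,TRUE,ref. 1,synthetic study record emulating the published 90-day design,transcribed for fixture use,control and recovery groups included
hc-yellow-no-13-rdt-1,hc-yellow-no-13,OP-hc-yellow-no-13,OECD_408,"Test animal/species=rat|Test animal/sex=male and female|Test animal/age value=7|Test animal/age unit=weeks|Test method/Test substance/identification=HC yellow No. 13|Test method/Test substance/purity=95%|Test method/Test condition/Oral administration/route=diet|Test method/Test condition/dose levels=0; 100; 300; 1000|Test method/Test condition/animals per group=10|Clinical biochemistry/Hepatocellular effect/total cholesterol=increased|Results/endpoints and methods=clinical biochemistry|Results/results description=described for all endpoints",,2011,FALSE,ref. 2,synthetic study record for a dietary design lacking stability data,transcribed for fixture use,
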