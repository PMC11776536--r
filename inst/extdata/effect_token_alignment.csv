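parameter,direction,token
ALP,increase,increased blood ALP concentration
GGT,increase,presence of GGT in blood
hepatic necrosis,increase,necrosis
hepatic necrosis,change,necrosis
triglycerides,increase,increased hepatic triglycerides
hepatic fat,increase,hepatic fat accumulation
cholesterol,increase,increased blood cholesterol concentration
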