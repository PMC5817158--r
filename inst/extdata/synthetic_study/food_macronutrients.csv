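food_item,protein_g,carbohydrate_g,lipid_g
lean vertebrate prey,0.990000,0.004000,0.001838
starchy root,0.004000,0.990000,0.001838
oily hard mast,0.004000,0.004000,0.454865
ungulate carcass,0.500000,0.020000,0.300000
insects,0.550000,0.100000,0.150000
graminoid,0.250000,0.600000,0.040000
forb,0.220000,0.650000,0.030000
fruit,0.050000,0.800000,0.060000
cereal crop,0.120000,0.780000,0.030000
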