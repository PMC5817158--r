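food_item,cf
lean vertebrate prey,2.000000
starchy root,0.300000
oily hard mast,1.700000
ungulate carcass,2.100000
insects,1.100000
graminoid,0.260000
forb,0.270000
fruit,1.300000
cereal crop,1.000000
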