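population_id,season,group,P,C,L
1.000000,spring,natural,0.403464,0.234153,0.362382
1.000000,summer,natural,0.327107,0.293442,0.379451
1.000000,autumn,natural,0.211106,0.481596,0.307298
2.000000,spring,natural,0.628667,0.061971,0.309362
2.000000,summer,natural,0.473865,0.272222,0.253912
2.000000,autumn,natural,0.171228,0.487940,0.340832
3.000000,spring,anthropogenic,0.477666,0.147632,0.374703
3.000000,summer,anthropogenic,0.153678,0.490379,0.355943
3.000000,autumn,anthropogenic,0.127478,0.288184,0.584338
4.000000,spring,natural,0.568320,0.122757,0.308923
4.000000,summer,natural,0.392649,0.102506,0.504845
4.000000,autumn,natural,0.365982,0.460182,0.173836
5.000000,spring,natural,0.510054,0.176704,0.313242
5.000000,summer,natural,0.575888,0.203476,0.220636
5.000000,autumn,natural,0.273472,0.519568,0.206960
6.000000,spring,natural,0.480095,0.162556,0.357349
6.000000,summer,natural,0.322681,0.439307,0.238012
6.000000,autumn,natural,0.212715,0.650327,0.136958
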