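population_id,season,food_item,pct_vol
1.000000,spring,lean vertebrate prey,13.764343
1.000000,spring,starchy root,26.917582
1.000000,spring,oily hard mast,21.365613
1.000000,spring,ungulate carcass,1.395911
1.000000,spring,insects,1.819479
1.000000,spring,graminoid,10.103903
1.000000,spring,forb,16.425707
1.000000,spring,fruit,3.683478
1.000000,spring,cereal crop,4.523985
1.000000,summer,lean vertebrate prey,7.865854
1.000000,summer,starchy root,40.037158
1.000000,summer,oily hard mast,20.126855
1.000000,summer,ungulate carcass,3.001996
1.000000,summer,insects,3.062516
1.000000,summer,graminoid,12.707460
1.000000,summer,forb,10.577352
1.000000,summer,fruit,0.733221
1.000000,summer,cereal crop,1.887588
1.000000,autumn,lean vertebrate prey,5.361688
1.000000,autumn,starchy root,63.920540
1.000000,autumn,oily hard mast,6.924463
1.000000,autumn,ungulate carcass,0.420864
1.000000,autumn,insects,2.535963
1.000000,autumn,graminoid,8.248264
1.000000,autumn,forb,9.029700
1.000000,autumn,fruit,1.260667
1.000000,autumn,cereal crop,2.297851
2.000000,spring,lean vertebrate prey,34.246226
2.000000,spring,starchy root,38.073156
2.000000,spring,oily hard mast,27.680618
2.000000,summer,lean vertebrate prey,15.952431
2.000000,summer,starchy root,42.593857
2.000000,summer,oily hard mast,9.860098
2.000000,summer,ungulate carcass,1.649860
2.000000,summer,insects,3.813648
2.000000,summer,graminoid,13.415695
2.000000,summer,forb,6.153807
2.000000,summer,fruit,3.613488
2.000000,summer,cereal crop,2.947114
2.000000,autumn,lean vertebrate prey,1.630543
2.000000,autumn,starchy root,63.329162
2.000000,autumn,oily hard mast,11.932222
2.000000,autumn,ungulate carcass,0.911851
2.000000,autumn,insects,0.792314
2.000000,autumn,graminoid,6.110312
2.000000,autumn,forb,9.284841
2.000000,autumn,fruit,2.259648
2.000000,autumn,cereal crop,3.749106
3.000000,spring,lean vertebrate prey,23.782566
3.000000,spring,starchy root,4.902052
3.000000,spring,oily hard mast,24.629746
3.000000,spring,ungulate carcass,2.288160
3.000000,spring,insects,3.134467
3.000000,spring,graminoid,18.897398
3.000000,spring,forb,15.828691
3.000000,spring,fruit,3.338852
3.000000,spring,cereal crop,3.198067
3.000000,summer,lean vertebrate prey,1.461422
3.000000,summer,starchy root,66.418546
3.000000,summer,oily hard mast,10.852944
3.000000,summer,ungulate carcass,0.478100
3.000000,summer,insects,0.842147
3.000000,summer,graminoid,5.191511
3.000000,summer,forb,9.094766
3.000000,summer,fruit,2.596310
3.000000,summer,cereal crop,3.064254
3.000000,autumn,lean vertebrate prey,1.289686
3.000000,autumn,starchy root,42.144498
3.000000,autumn,oily hard mast,18.848822
3.000000,autumn,ungulate carcass,1.425511
3.000000,autumn,insects,2.794752
3.000000,autumn,graminoid,11.987524
3.000000,autumn,forb,16.271256
3.000000,autumn,fruit,3.283419
3.000000,autumn,cereal crop,1.954532
4.000000,spring,lean vertebrate prey,41.415225
4.000000,spring,starchy root,16.805902
4.000000,spring,oily hard mast,18.071106
4.000000,spring,ungulate carcass,0.187702
4.000000,spring,insects,1.869928
4.000000,spring,graminoid,8.863830
4.000000,spring,forb,6.836938
4.000000,spring,fruit,3.504410
4.000000,spring,cereal crop,2.444960
4.000000,summer,lean vertebrate prey,20.318771
4.000000,summer,starchy root,20.256423
4.000000,summer,oily hard mast,33.411224
4.000000,summer,ungulate carcass,0.398952
4.000000,summer,insects,1.808991
4.000000,summer,graminoid,9.842616
4.000000,summer,forb,8.244238
4.000000,summer,fruit,3.641758
4.000000,summer,cereal crop,2.077028
4.000000,autumn,lean vertebrate prey,7.116030
4.000000,autumn,starchy root,62.578254
4.000000,autumn,oily hard mast,3.051950
4.000000,autumn,ungulate carcass,0.514932
4.000000,autumn,insects,1.703117
4.000000,autumn,graminoid,11.028841
4.000000,autumn,forb,8.416279
4.000000,autumn,fruit,3.929190
4.000000,autumn,cereal crop,1.661406
5.000000,spring,lean vertebrate prey,23.388196
5.000000,spring,starchy root,18.824552
5.000000,spring,oily hard mast,12.287410
5.000000,spring,ungulate carcass,1.661145
5.000000,spring,insects,4.721073
5.000000,spring,graminoid,14.844192
5.000000,spring,forb,13.939151
5.000000,spring,fruit,5.230222
5.000000,spring,cereal crop,5.104059
5.000000,summer,lean vertebrate prey,23.979168
5.000000,summer,starchy root,22.448176
5.000000,summer,oily hard mast,8.314060
5.000000,summer,ungulate carcass,1.837498
5.000000,summer,insects,5.958215
5.000000,summer,graminoid,14.219655
5.000000,summer,forb,16.934513
5.000000,summer,fruit,1.991130
5.000000,summer,cereal crop,4.317585
5.000000,autumn,lean vertebrate prey,2.832625
5.000000,autumn,starchy root,67.929371
5.000000,autumn,oily hard mast,4.865717
5.000000,autumn,ungulate carcass,0.777459
5.000000,autumn,insects,2.522486
5.000000,autumn,graminoid,5.280357
5.000000,autumn,forb,12.429662
5.000000,autumn,fruit,1.517238
5.000000,autumn,cereal crop,1.845086
6.000000,spring,lean vertebrate prey,23.437248
6.000000,spring,starchy root,7.899876
6.000000,spring,oily hard mast,22.674823
6.000000,spring,ungulate carcass,2.918551
6.000000,spring,insects,3.538345
6.000000,spring,graminoid,17.447976
6.000000,spring,forb,15.144391
6.000000,spring,fruit,3.571187
6.000000,spring,cereal crop,3.367603
6.000000,summer,lean vertebrate prey,9.936578
6.000000,summer,starchy root,59.270628
6.000000,summer,oily hard mast,5.109411
6.000000,summer,ungulate carcass,0.727381
6.000000,summer,insects,4.343469
6.000000,summer,graminoid,9.783515
6.000000,summer,forb,7.568438
6.000000,summer,fruit,1.976420
6.000000,summer,cereal crop,1.284161
6.000000,autumn,lean vertebrate prey,5.306616
6.000000,autumn,starchy root,75.137660
6.000000,autumn,oily hard mast,1.676861
6.000000,autumn,ungulate carcass,0.329427
6.000000,autumn,insects,0.572885
6.000000,autumn,graminoid,7.701419
6.000000,autumn,forb,8.123313
6.000000,autumn,fruit,0.441568
6.000000,autumn,cereal crop,0.710250
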