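"trial_id","analyte","chamber_volume_ml","flow_ml_min","mass_g","midpoint_hr","duration_min","conc_mg_m3"
"dark_fine_1","diacetyl",114,39.4,5.2,0.0333333333333333,0.5,4.23447730267278
"dark_fine_1","diacetyl",114,39.4,5.2,0.0666666666666667,0.5,6.48521204733626
"dark_fine_1","diacetyl",114,39.4,5.2,0.1,0.5,6.9295598620731
"dark_fine_1","diacetyl",114,39.4,5.2,0.133333333333333,0.5,7.53780205411074
"dark_fine_1","diacetyl",114,39.4,5.2,0.166666666666667,0.5,7.58536420506699
"dark_fine_1","diacetyl",114,39.4,5.2,0.25,1,7.48074242322498
"dark_fine_1","diacetyl",114,39.4,5.2,0.583333333333333,1,5.21240009554204
"dark_fine_1","diacetyl",114,39.4,5.2,1,1,3.39229054059416
"dark_fine_2","diacetyl",114,39.4,5.2,0.0333333333333333,0.5,3.70303096411172
"dark_fine_2","diacetyl",114,39.4,5.2,0.0666666666666667,0.5,5.61457765335412
"dark_fine_2","diacetyl",114,39.4,5.2,0.1,0.5,5.75619489956288
"dark_fine_2","diacetyl",114,39.4,5.2,0.133333333333333,0.5,7.10787113628276
"dark_fine_2","diacetyl",114,39.4,5.2,0.166666666666667,0.5,6.89113115554329
"dark_fine_2","diacetyl",114,39.4,5.2,0.25,1,6.57880169226972
"dark_fine_2","diacetyl",114,39.4,5.2,0.583333333333333,1,4.87118417600403
"dark_fine_2","diacetyl",114,39.4,5.2,1,1,3.33759247646395
"dark_fine_3","diacetyl",114,39.4,5.2,0.0333333333333333,0.5,4.74434492245732
"dark_fine_3","diacetyl",114,39.4,5.2,0.0666666666666667,0.5,7.22609504488251
"dark_fine_3","diacetyl",114,39.4,5.2,0.1,0.5,7.68967762058304
"dark_fine_3","diacetyl",114,39.4,5.2,0.133333333333333,0.5,8.3758062125391
"dark_fine_3","diacetyl",114,39.4,5.2,0.166666666666667,0.5,7.66966468975721
"dark_fine_3","diacetyl",114,39.4,5.2,0.25,1,7.80777053359334
"dark_fine_3","diacetyl",114,39.4,5.2,0.583333333333333,1,5.60008543738016
"dark_fine_3","diacetyl",114,39.4,5.2,1,1,3.69834062520375
"light_fine_1","2,3-pentanedione",114,39.4,5.2,0.0333333333333333,0.5,4.78532808322586
"light_fine_1","2,3-pentanedione",114,39.4,5.2,0.0666666666666667,0.5,7.41249410674662
"light_fine_1","2,3-pentanedione",114,39.4,5.2,0.1,0.5,8.49125911748548
"light_fine_1","2,3-pentanedione",114,39.4,5.2,0.133333333333333,0.5,8.49200184679211
"light_fine_1","2,3-pentanedione",114,39.4,5.2,0.166666666666667,0.5,9.18696671243675
"light_fine_1","2,3-pentanedione",114,39.4,5.2,0.25,1,8.55900889928584
"light_fine_1","2,3-pentanedione",114,39.4,5.2,0.583333333333333,1,6.60467446331408
"light_fine_1","2,3-pentanedione",114,39.4,5.2,1,1,5.33852321531134
"light_fine_2","2,3-pentanedione",114,39.4,5.2,0.0333333333333333,0.5,3.03307394378264
"light_fine_2","2,3-pentanedione",114,39.4,5.2,0.0666666666666667,0.5,4.64631898642185
"light_fine_2","2,3-pentanedione",114,39.4,5.2,0.1,0.5,5.45669650013444
"light_fine_2","2,3-pentanedione",114,39.4,5.2,0.133333333333333,0.5,6.03785194618663
"light_fine_2","2,3-pentanedione",114,39.4,5.2,0.166666666666667,0.5,5.72296761995208
"light_fine_2","2,3-pentanedione",114,39.4,5.2,0.25,1,5.5393506040743
"light_fine_2","2,3-pentanedione",114,39.4,5.2,0.583333333333333,1,4.10784789199705
"light_fine_2","2,3-pentanedione",114,39.4,5.2,1,1,2.77526423717297
"light_fine_3","2,3-pentanedione",114,39.4,5.2,0.0333333333333333,0.5,6.25588843851737
"light_fine_3","2,3-pentanedione",114,39.4,5.2,0.0666666666666667,0.5,9.3425075709836
"light_fine_3","2,3-pentanedione",114,39.4,5.2,0.1,0.5,10.8771753157273
"light_fine_3","2,3-pentanedione",114,39.4,5.2,0.133333333333333,0.5,11.6655236302951
"light_fine_3","2,3-pentanedione",114,39.4,5.2,0.166666666666667,0.5,11.2060476498932
"light_fine_3","2,3-pentanedione",114,39.4,5.2,0.25,1,11.0079299809881
"light_fine_3","2,3-pentanedione",114,39.4,5.2,0.583333333333333,1,7.20041003270031
"light_fine_3","2,3-pentanedione",114,39.4,5.2,1,1,5.33395043475766
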