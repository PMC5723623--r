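genus,crown_node,crown_mean,crown_lo,crown_hi,stem_node,stem_mean,stem_lo,stem_hi,top_area,top_prob,clade
Acidoton,880,31.74,13.65,50.99,879,42.49,23.65,60.72,RW,0.38,Acidoton
Anacaona,628,12.71,4.05,22.29,627,27.67,17.54,36.97,AN,0.65,Anacaona
Arcoa,640,34.09,26.56,40.05,637,38.24,34.68,41.72,RW,0.80,Arcoa
Bonania,926,9.92,2.81,17.60,925,19.41,8.32,30.44,AN,0.19,Bonania-Grimmeodendron
Broughtonia,1136,19.42,10.91,27.63,1135,26.73,18.45,36.05,AN,0.83,Broughtonia-Psychilis-Quisqueya-Tetramicra
Brya,851,13.72,3.52,24.82,850,44.17,28.59,57.89,SA,0.94,Brya
Calycogonium,957,26.81,9.67,44.44,956,47.27,26.64,67.79,SA,0.53,Calycogonium
Chascotheca,952,32.86,15.37,52.74,951,56.43,31.72,80.80,RW,0.26,Chascotheca
Cubanola,1004,17.65,9.73,26.12,1002,20.25,11.98,28.28,AN,0.97,Cubanola
Dendropemon,1083,20.45,5.34,37.22,1082,44.19,20.76,70.21,CA,0.65,Dendropemon
Dilomilis,1199,18.74,5.10,35.04,1111,52.80,36.69,69.27,AN,0.93,Dilomilis-Neocogniauxia
Ditta,937,15.09,5.32,25.90,936,28.50,13.42,43.68,RW,0.80,Ditta
Domingoa,1144,15.009,5.61,24.63,1116,30.67,24.48,34.96,AN,0.57,Domingoa
Grimmeodendron,927,6.61,0.99,12.81,925,19.41,8.32,30.44,AN,0.19,Bonania-Grimmeodendron
Hebestigma,806,53.12,33.13,72.98,716,105.48,88.57,123.62,SA,0.29,Hebestigma
Hemithrinax,1210,6.07,1.71,10.28,1209,9.35,3.68,14.72,AN,0.98,Hemithrinax
Leptocereus,979,9.07,2.43,16.32,978,11.12,3.35,17.42,SA,0.89,Leptocereus
Lasiocroton,891,22.59,11.16,35.23,890,28.85,18.81,41.40,CA,0.54,Lasiocroton-Leucocroton
Leucocroton,891,22.59,11.16,35.23,890,28.85,18.81,41.40,CA,0.54,Lasiocroton-Leucocroton
Microcycas,1216,28.23,12.43,45.78,1215,51,26.15,79.07,AN,0.95,Microcycas
Neobracea,1015,6.49,0.81,13.42,1014,35.45,18.29,53.39,ANRW,0.61,Neobracea
Neocogniauxia,1199,18.74,5.10,35.04,1111,52.80,36.69,69.27,AN,0.93,Dilomilis-Neocogniauxia
Penelopeia,627,20.91,9.58,31.80,626,27.67,17.54,36.97,CA,0.39,Penelopeia
Picrodendron,942,19.13,12.37,26.11,941,23.93,16.27,30.93,RW,0.48,Picrodendron
Pictetia,842,13.96,5.15,23.03,841,17.67,7.47,27.37,AN,0.45,Pictetia
Poitea,826,11.50,4.63,18.89,823,17.10,8.50,26.01,AN,0.25,Poitea
Psychilis,1140,15.93,8.51,24.31,1135,26.73,18.45,36.05,AN,0.83,Broughtonia-Psychilis-Quisqueya-Tetramicra
Quisqueya,1142,12.08,4.73,19.92,1135,26.73,18.45,36.05,AN,0.83,Broughtonia-Psychilis-Quisqueya-Tetramicra
Rhodopis,797,17.47,6.42,29.48,796,21.89,10.33,33.92,SA,0.14,Rhodopis
Stahlia,666,3.40,0.0078,8.50,665,8.64,1.86,15.97,CA,0.67,Stahlia
Tetramicra,1142,12.08,4.73,19.92,1135,26.73,18.45,36.05,AN,0.83,Broughtonia-Psychilis-Quisqueya-Tetramicra
Zombia,1209,8.13,3.03,13.74,1208,9.35,3.68,14.72,AN,0.79,Zombia
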