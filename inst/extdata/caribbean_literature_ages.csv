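genus,crown,stem,area
Acidoton,1.7,2.6,SA
Anacaona,13,17,SA
Arcoa,34,,
Bonania,41.6,46.39,MX-SA-MS
Broughtonia,15.68,20.74,
Brya,41.9,47.2,
Cubanola,19.2,47.3,AN
Dilomilis,16.01,46.72,
Ditta,95,105,
Domingoa,19.34,20.9,
Hebestigma,38.1,48.3,
Hemithrinax,6.99,17.54,AN
Leptocereus,2.8,4.8,SA
Lasiocroton,1.17,10.76,AN
Leucocroton,5.27,10.76,AN
Microcycas,36.5,60.32,AF-CA
Neocogniauxia,16.01,46.72,
Penelopeia,13,17,SA
Pictetia,14.5,45.6,
Poitea,9.2,16.4,
Psychilis,15.68,20.74,
Quisqueya,15.68,20.74,
Tetramicra,15.68,20.74,
Zombia,3.75,21.7,AN
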