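name,cas,rfc,iur,oel_china_twa,oel_acgih_twa,carcinogenicity,ld50_oral,lc50_inhal,risk_phrases,physical_form,dustiness_band,volatility_band,hr_override,notes
Silicious dust,14808-60-7,,,0.7,0.025,IARC-1,,,R49;R48/20,solid,high,,,respirable crystalline silica; OELs per GBZ 2.1 / ACGIH
Other dust,,,,8,10,none,,,R36/37,solid,medium,,1,placeholder OEL for unspecified nuisance dust; HR override: low-toxicity nuisance dust
Iron dust,1309-37-1,,,3,5,none,,,R36/37,solid,low,,1,placeholder OEL (iron oxide dust); HR override: low-toxicity nuisance dust
Welding fume,,,,4,5,IARC-1,,,R20,solid,low,,,
Manganese and inorganic compounds,7439-96-5,0.05,,0.15,0.02,none,9000,,R20/22;R48/20,solid,low,,4,PC-TWA as MnO2; HR override per semi-quantitative practice
Nitrogen oxides,10102-44-0,,,5,5.6,none,,300,R23;R37,gas,,,,as NO2
Grinding wheel dust,,,,8,10,none,,,R36/37,solid,low,,1,HR override: low-toxicity nuisance dust
Benzene,71-43-2,30,,6,1.6,IARC-1,930,,R45;R46;R11;R48/23/24/25,liquid,,medium,,
Xylene,1330-20-7,100,,50,434,IARC-3,3500,,R10;R20/21;R38,liquid,,medium,,
Ethyl acetate,141-78-6,3500,,200,1440,none,5620,,R11;R36;R66;R67,liquid,,high,,
Iron-ore dust,,,,3,5,none,,,R36/37,solid,low,,1,placeholder OEL (iron-bearing mineral dust); HR override: low-toxicity nuisance dust
Talc dust,14807-96-6,,,3,2,none,,,R36/37,solid,low,,1,asbestos-free talc; HR override: low-toxicity nuisance dust
Gasoline,86290-81-5,,,300,890,none,14000,,R45;R11;R38;R65,liquid,,high,2,HR override reflects aromatic content of petrol vapour
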