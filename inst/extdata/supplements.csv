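product,kcal_per_100g,price_per_kg,protein_pct_kcal,fat_pct_kcal
RUTF,557,2.18,10,59
CSB,376,0.481,18,17
maize meal (yellow),366,0.296,9,4
rice (white),365,0.540,8,2
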