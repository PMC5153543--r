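condition,frequency
Papular pruritic eruptions,1
Extensive molluscum contagiosum,1
Recurrent oral ulcerations (2 or more episodes in 6 months),1
Unexplained persistent parotid enlargement,2
"Recurrent or chronic upper respiratory tract infections (otitis media, otorrhoea, sinusitis, tonsillitis)",1
Moderate unexplained malnutrition not adequately responding to standard therapy,83
Unexplained persistent diarrhoea (>14 days),163
"Unexplained persistent fever (above 37.5 intermittent or constant, for >1 month)",176
Persistent oral candidiasis (outside neonatal period),74
Oral hairy leukoplakia,1
Acute necrotizing ulcerative gingivitis/periodontitis,1
Pulmonary tuberculosis,70
Severe recurrent presumed bacterial pneumonia,79
"Unexplained anaemia (<8 gm/dL), neutropenia (<500/mm3), or thrombocytopenia (<50,000/mm3) for >1 month",10
Symptomatic lymphoid interstitial pneumonia (LIP),4
TB lymphadenitis,1
Unexplained severe wasting or severe malnutrition not adequately responding to therapy,72
Recurrent severe presumed bacterial infections,1
"Chronic herpes simplex infection (orolabial or cutaneous, for >1 month, visceral at any site)",1
Extrapulmonary TB,5
Kaposi's sarcoma,2
"Oesophageal candidiasis (or candida of trachea, bronchi, or lungs)",1
Extrapulmonary cryptococcosis including meningitis,1
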