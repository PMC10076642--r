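block,category,count
N,Total,388
Age (years),<=25,10
Age (years),26-50,50
Age (years),51-75,60
Age (years),>=76,4
Age (years),Unknown,264
Gender,female,171
Gender,male,124
Gender,Unknown,93
Reporting country,United States,222
Reporting country,Other countries,104
Reporting country,Unknown,62
Reporting year,2015-2016,28
Reporting year,2017-2018,133
Reporting year,2019-2020,133
Reporting year,2021-2022,94
Primary suspect drug,secukinumab,348
Primary suspect drug,ixekizumab,36
Primary suspect drug,brodalumab,4
Outcome,Death,9
Outcome,Life-threatening,6
Outcome,Hospitalization-initial or prolonged,84
Outcome,Disability,3
Outcome,Required intervention,3
Outcome,Other medical significant condition,224
Outcome,Unknown,59
Indication,Ankylosing spondylitis,51
Indication,Psoriasis,100
Indication,Psoriatic arthropathy,53
Indication,Others,10
Indication,Unknown,174
Bowel disease,All IBD,268
Bowel disease,Colitis ulcerative,87
Bowel disease,Crohn's disease,96
Bowel disease,Inflammatory bowel disease,85
Bowel disease,All colitis,120
Onset time of symptoms (months),<1,6
Onset time of symptoms (months),1-3,20
Onset time of symptoms (months),3-6,12
Onset time of symptoms (months),6-12,15
Onset time of symptoms (months),12-24,8
Onset time of symptoms (months),>24,9
Onset time of symptoms (months),Unknown,318
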