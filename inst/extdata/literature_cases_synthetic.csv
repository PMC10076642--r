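case_id,source_kind,sex,age_years,region,drug,preexisting_ibd,family_history_ibd,indication,smoking,prior_tnf,onset_months,ibd_class,symptoms,wbc,crp,esr,fecal_calprotectin,ct_findings,colonoscopy_findings,histopathology_findings,therapy,outcome,relief_weeks
LC01,case_report,female,19,USA,secukinumab,TRUE,FALSE,PsO,yes,adalimumab,0.47,UC,diarrhea;bloody_diarrhea;chills,elevated,elevated,elevated,elevated,bowel_wall_thickening,deep_ulcerations;superficial_ulceration,chronic_inflammation;crypt_abscesses,corticosteroids,recovered,0.5
LC02,case_report,female,26,USA,secukinumab,TRUE,FALSE,PsO,yes,adalimumab,0.5,UC,diarrhea;bloody_diarrhea;chills,elevated,elevated,elevated,elevated,bowel_wall_thickening,deep_ulcerations;superficial_ulceration,chronic_inflammation;crypt_abscesses,corticosteroids,recovered,1
LC03,case_report,female,27,USA,secukinumab,TRUE,FALSE,PsO,yes,adalimumab,0.6,UC,diarrhea;bloody_diarrhea;chills,elevated,elevated,elevated,elevated,bowel_wall_thickening,deep_ulcerations;superficial_ulceration,chronic_inflammation;granulomatous_lesions,corticosteroids,recovered,1.5
LC04,case_report,female,29,USA,secukinumab,FALSE,TRUE,PsO,yes,adalimumab,0.8,UC,diarrhea;bloody_diarrhea;chills,elevated,elevated,elevated,elevated,bowel_wall_thickening,deep_ulcerations;superficial_ulceration,chronic_inflammation;granulomatous_lesions,corticosteroids,recovered,2
LC05,case_report,female,30,USA,secukinumab,FALSE,TRUE,PsO,yes,adalimumab,0.9,UC,diarrhea;bloody_diarrhea;nausea,elevated,elevated,elevated,,bowel_wall_thickening,deep_ulcerations;superficial_ulceration,chronic_inflammation;granulomatous_lesions,corticosteroids,recovered,2.5
LC06,case_report,female,31,USA,secukinumab,FALSE,TRUE,PsO,yes,adalimumab,1,UC,diarrhea;bloody_diarrhea;abdominal_pain;nausea,elevated,elevated,elevated,,pancolitis,deep_ulcerations;edematous,chronic_inflammation;granulomatous_lesions,corticosteroids,recovered,3
LC07,case_report,female,33,USA,secukinumab,FALSE,TRUE,PsO,yes,adalimumab,1.2,UC,diarrhea;bloody_diarrhea;abdominal_pain;nausea,elevated,elevated,normal,,pancolitis,deep_ulcerations;edematous,chronic_inflammation;granulomatous_lesions,corticosteroids,recovered,3
LC08,case_report,female,34,USA,secukinumab,FALSE,TRUE,PsO,yes,adalimumab,1.5,UC,diarrhea;bloody_diarrhea;abdominal_pain;nausea,normal,elevated,,,colon_perforated,deep_ulcerations;edematous,chronic_inflammation;granulomatous_lesions,corticosteroids,recovered,3.5
LC09,case_report,female,35,USA,secukinumab,FALSE,FALSE,PsO,no,adalimumab,1.8,UC,diarrhea;bloody_diarrhea;abdominal_pain,,elevated,,,normal,deep_ulcerations;edematous,chronic_inflammation;granulomatous_lesions,corticosteroids,recovered,3.5
LC10,case_report,female,36,USA,secukinumab,FALSE,FALSE,PsO,no,adalimumab,2,UC,diarrhea;bloody_diarrhea;abdominal_pain;fever,,elevated,,,normal,deep_ulcerations;edematous,chronic_inflammation,corticosteroids,recovered,3.9
LC11,case_report,female,37,USA,secukinumab,FALSE,FALSE,PsO,no,adalimumab,2.2,UC,diarrhea;bloody_diarrhea;abdominal_pain;fever,,elevated,,,,deep_ulcerations;friable_mucosa,chronic_inflammation,corticosteroids_plus_tnf,recovered,4
LC12,case_report,female,38,Europe,secukinumab,FALSE,FALSE,PsO,no,adalimumab,2.5,UC,diarrhea;bloody_diarrhea;abdominal_pain;fever,,elevated,,,,deep_ulcerations;friable_mucosa,cryptitis,corticosteroids_plus_tnf,recovered,4.5
LC13,case_report,female,39,Europe,secukinumab,FALSE,FALSE,PsO,not_mentioned,adalimumab,2.8,UC,diarrhea;bloody_diarrhea;abdominal_pain;fever,,elevated,,,,deep_ulcerations;friable_mucosa,cryptitis,corticosteroids_plus_tnf,recovered,6
LC14,case_report,female,40,Europe,secukinumab,FALSE,FALSE,PsO,not_mentioned,etanercept,2.9,CD,diarrhea;bloody_diarrhea;abdominal_pain;fever,,elevated,,,,active_inflammation;friable_mucosa,cryptitis,corticosteroids_plus_tnf,recovered,8
LC15,case_report,female,41,Europe,secukinumab,FALSE,FALSE,PsO,not_mentioned,etanercept,3,CD,diarrhea;bloody_diarrhea;abdominal_pain;fever,,elevated,,,,active_inflammation;absent_vascular_pattern,cryptitis,corticosteroids_plus_tnf,recovered,12
LC16,case_report,female,41,Europe,secukinumab,FALSE,FALSE,PsO,not_mentioned,etanercept,3.5,CD,diarrhea;bloody_diarrhea;abdominal_pain;fever,,elevated,,,,active_inflammation;absent_vascular_pattern,cryptitis,corticosteroids_plus_tnf,recovered,
LC17,case_report,female,42,Europe,secukinumab,FALSE,FALSE,PsO,not_mentioned,etanercept,4,CD,diarrhea;bloody_diarrhea;abdominal_pain;fever,,,,,,active_inflammation;absent_vascular_pattern,cryptitis,tnf_antagonist,recovered,
LC18,case_report,male,42,Europe,secukinumab,FALSE,FALSE,PsO,not_mentioned,etanercept,4.5,CD,diarrhea;abdominal_pain;fever;weight_loss,,,,,,active_inflammation;absent_vascular_pattern,cryptitis,tnf_antagonist,recovered,
LC19,case_report,male,43,Europe,secukinumab,FALSE,FALSE,PsO,not_mentioned,etanercept,5,CD,diarrhea;abdominal_pain;fever;weight_loss,,,,,,active_inflammation;hemorrhagic,cryptitis,tnf_antagonist,recovered,
LC20,case_report,male,44,Europe,secukinumab,FALSE,FALSE,PsO,not_mentioned,etanercept,5.5,CD,diarrhea;abdominal_pain;fever;weight_loss,,,,,,active_inflammation;hemorrhagic,crypt_abscesses,tnf_antagonist,recovered,
LC21,case_report,male,46,Europe,secukinumab,FALSE,FALSE,PsA,not_mentioned,etanercept,5.9,CD,diarrhea;abdominal_pain;fever;weight_loss,,,,,,active_inflammation;hemorrhagic,crypt_abscesses,tnf_antagonist,recovered,
LC22,case_report,male,47,Europe,secukinumab,FALSE,FALSE,PsA,not_mentioned,etanercept,6.5,CD,diarrhea;abdominal_pain;weight_loss,,,,,,erythematous_mucosa,crypt_abscesses,tnf_antagonist,recovered,
LC23,case_report,male,48,Europe,secukinumab,FALSE,FALSE,PsA,not_mentioned,etanercept,8,CD,diarrhea,,,,,,erythematous_mucosa,crypt_abscesses,corticosteroids_plus_5asa,recovered,
LC24,case_report,male,50,Europe,secukinumab,FALSE,FALSE,PsA,not_mentioned,etanercept,11,unclassified,diarrhea,,,,,,erythematous_mucosa,crypt_abscesses,corticosteroids_plus_5asa,recovered,
LC25,case_report,male,51,Canada,secukinumab,FALSE,FALSE,PsO_and_PsA,not_mentioned,,14,unclassified,diarrhea,,,,,,erythematous_mucosa,crypt_abscesses,corticosteroids_plus_5asa,recovered,
LC26,case_series,male,54,Canada,secukinumab,FALSE,FALSE,PsO_and_PsA,not_mentioned,,20,unclassified,diarrhea,,,,,,erythematous_mucosa,,corticosteroids_plus_5asa,recovered,
LC27,case_series,male,58,Canada,secukinumab,FALSE,FALSE,PsO_and_PsA,not_mentioned,,48,unclassified,diarrhea,,,,,,erythematous_mucosa,,ustekinumab,recovered,
LC28,case_series,male,60,Canada,ixekizumab,FALSE,FALSE,AS,not_mentioned,,,unclassified,diarrhea,,,,,,superficial_ulceration,,ustekinumab,relapse,
LC29,case_series,male,63,Canada,ixekizumab,FALSE,FALSE,AS,not_mentioned,,,,abdominal_pain,,,,,,,,corticosteroids_plus_ustekinumab,relapse,
LC30,,male,65,Canada,ixekizumab,FALSE,FALSE,AS,not_mentioned,,,,abdominal_pain,,,,,,,,five_asa,,
LC31,,male,68,Asia,ixekizumab,FALSE,FALSE,AS,not_mentioned,,,,diarrhea,,,,,,,,none,,
LC32,,male,72,Asia,ixekizumab,FALSE,FALSE,AS,not_mentioned,,,,diarrhea,,,,,,,,,,
LC33,,male,75,other,ixekizumab,FALSE,FALSE,AS,not_mentioned,,,,asymptomatic,,,,,,,,,,
LC34,,male,76,,ixekizumab,FALSE,FALSE,AS,not_mentioned,,,,,,,,,,,,,,
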