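patient_id,age_years,bmi_kg_m2,underlying_disease,previous_pelvic_surgery,nac,procedure,surgical_time_min,preop_hb_g_dl,postop_hb_g_dl,ebl_ml,lowest_map_mmhg,lowest_hr_bpm,events
P0001,38.1,26.9,FALSE,FALSE,FALSE,radical_hysterectomy,195.2,11.7,11.1,84.1,68.5,59.5,
P0002,44.4,24.8,FALSE,FALSE,FALSE,radical_hysterectomy,190.5,11.9,10.9,421,62.3,52.3,bleeding_ge_300:pharmacological
P0003,28.8,22.8,FALSE,FALSE,FALSE,radical_hysterectomy,176.7,13.8,14.3,56.6,70.4,60.7,
P0004,30.3,19.9,FALSE,FALSE,FALSE,radical_trachelectomy,135.7,11.1,11.8,72.4,67.4,59.3,
P0005,56,20.4,FALSE,TRUE,FALSE,radical_hysterectomy,174.3,12,11.3,21.8,44.9,47.8,
P0006,34.7,21.9,FALSE,TRUE,FALSE,radical_hysterectomy,120.3,13.6,12.9,101.9,61.6,70.2,
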