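feature_key,display
onset_midlife,Symptom onset in midlife
symptoms_slowly_progressive,Slowly progressive symptoms
smoking_history,History of tobacco smoking or other smoke exposure
onset_early_life,Symptom onset early in life (often childhood)
symptoms_vary_day_to_day,Symptoms vary widely from day to day
symptoms_worse_night_morning,Symptoms worse at night or early morning
allergy_rhinitis_eczema,"Allergy, rhinitis and/or eczema present"
family_history_asthma,Family history of asthma
obesity_coexistence,Coexisting obesity
xray_dilated_heart,Dilated heart on chest X-ray
pulmonary_edema,Pulmonary edema on chest X-ray
volume_restriction,Volume restriction (not airflow limitation) on pulmonary function tests
purulent_sputum_large_volume,Large volumes of purulent sputum
bacterial_infection,Associated bacterial infection
bronchial_dilatation,Bronchial dilatation on radiograph/CT
bronchial_wall_thickening,Bronchial wall thickening on radiograph/CT
onset_all_ages,Onset at any age
xray_lung_infiltrate,Lung infiltrate on chest X-ray
microbiological_confirmation,Microbiological confirmation
high_local_tb_prevalence,High local tuberculosis prevalence
onset_younger_age,Onset at a younger age
nonsmoker,Nonsmoker
rheumatoid_arthritis_or_fume_exposure,History of rheumatoid arthritis or acute fume exposure
post_transplantation,After lung or bone-marrow transplantation
ct_expiratory_hypodense_areas,Hypodense areas on expiratory CT
asian_descent,Asian descent
male_nonsmoker_predominance,Male predominance among nonsmokers
chronic_sinusitis,Chronic sinusitis
centrilobular_nodules_hyperinflation,Diffuse small centrilobular nodular opacities with hyperinflation
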