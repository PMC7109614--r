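diagnosis,feature_key,source_text
COPD,onset_midlife,Onset in midlife
COPD,symptoms_slowly_progressive,Symptoms slowly progressive
COPD,smoking_history,History of tobacco smoking or exposure to other types of smoke
asthma,onset_early_life,Onset early in life (often in childhood)
asthma,symptoms_vary_day_to_day,Symptoms vary widely from day to day
asthma,symptoms_worse_night_morning,Symptoms worse at night/early morning
asthma,allergy_rhinitis_eczema,"Allergy, rhinitis, and/or eczema also present"
asthma,family_history_asthma,Family history of asthma
asthma,obesity_coexistence,Obesity coexistence
congestive_heart_failure,xray_dilated_heart,Chest X-ray shows dilated heart
congestive_heart_failure,pulmonary_edema,Chest X-ray shows pulmonary edema
congestive_heart_failure,volume_restriction,"Pulmonary function tests indicate volume restriction, not airflow limitation"
bronchiectasis,purulent_sputum_large_volume,Large volumes of purulent sputum
bronchiectasis,bacterial_infection,Commonly associated with bacterial infection
bronchiectasis,bronchial_dilatation,Chest radiograph/CT scans show bronchial dilatation
bronchiectasis,bronchial_wall_thickening,Chest radiograph/CT scans show bronchial wall thickening
tuberculosis,onset_all_ages,Onset at all ages
tuberculosis,xray_lung_infiltrate,Chest X-ray shows lung infiltrate
tuberculosis,microbiological_confirmation,Microbiological confirmation
tuberculosis,high_local_tb_prevalence,High local prevalence of tuberculosis
obliterative_bronchiolitis,onset_younger_age,Onset at younger age
obliterative_bronchiolitis,nonsmoker,Nonsmokers
obliterative_bronchiolitis,rheumatoid_arthritis_or_fume_exposure,May have history of rheumatoid arthritis or acute fume exposure
obliterative_bronchiolitis,post_transplantation,Seen after lung or bone marrow transplantation
obliterative_bronchiolitis,ct_expiratory_hypodense_areas,CT on expiration shows hypodense areas
diffuse_panbronchiolitis,asian_descent,Predominantly seen in patients of Asian descent
diffuse_panbronchiolitis,male_nonsmoker_predominance,Most patients are male and nonsmokers
diffuse_panbronchiolitis,nonsmoker,Most patients are male and nonsmokers
diffuse_panbronchiolitis,chronic_sinusitis,Almost all cases involve chronic sinusitis
diffuse_panbronchiolitis,centrilobular_nodules_hyperinflation,Chest X-ray and HRCT show diffuse small centrilobular nodular opacities and hyperinflation
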