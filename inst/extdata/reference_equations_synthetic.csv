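source,sex,group,age_min,age_max,height_min,height_max,ratio_b0,ratio_b_age,ratio_see,fev1_b0,fev1_b_age,fev1_b_height,fev1_see,fvc_b0,fvc_b_age,fvc_b_height,fvc_see
copdflow-synthetic-v1,male,european,18,95,140,210,88.0,-0.20,5.5,-2.0,-0.025,0.040,0.45,-3.0,-0.022,0.050,0.55
copdflow-synthetic-v1,female,european,18,95,130,200,90.5,-0.19,5.8,-1.6,-0.022,0.034,0.38,-2.2,-0.020,0.042,0.46
copdflow-synthetic-v1,male,other,18,95,140,210,87.0,-0.20,5.6,-2.1,-0.025,0.039,0.45,-3.1,-0.022,0.049,0.55
copdflow-synthetic-v1,female,other,18,95,130,200,89.5,-0.19,5.9,-1.7,-0.022,0.033,0.38,-2.3,-0.020,0.041,0.46
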