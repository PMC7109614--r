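source,component,points,lower,upper,closed
bode-published-2004,fev1_pct,0,65,Inf,left
bode-published-2004,fev1_pct,1,50,65,left
bode-published-2004,fev1_pct,2,36,50,left
bode-published-2004,fev1_pct,3,-Inf,36,left
bode-published-2004,six_mwd,0,350,Inf,left
bode-published-2004,six_mwd,1,250,350,left
bode-published-2004,six_mwd,2,150,250,left
bode-published-2004,six_mwd,3,-Inf,150,left
bode-published-2004,mmrc,0,0,2,left
bode-published-2004,mmrc,1,2,3,left
bode-published-2004,mmrc,2,3,4,left
bode-published-2004,mmrc,3,4,Inf,left
bode-published-2004,bmi,0,21,Inf,right
bode-published-2004,bmi,1,-Inf,21,right
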