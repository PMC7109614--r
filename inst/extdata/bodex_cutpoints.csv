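source,component,points,lower,upper,closed
bodex-published-2009,fev1_pct,0,65,Inf,left
bodex-published-2009,fev1_pct,1,50,65,left
bodex-published-2009,fev1_pct,2,36,50,left
bodex-published-2009,fev1_pct,3,-Inf,36,left
bodex-published-2009,exacerbations,0,-Inf,1,left
bodex-published-2009,exacerbations,1,1,3,left
bodex-published-2009,exacerbations,2,3,Inf,left
bodex-published-2009,mmrc,0,0,2,left
bodex-published-2009,mmrc,1,2,3,left
bodex-published-2009,mmrc,2,3,4,left
bodex-published-2009,mmrc,3,4,Inf,left
bodex-published-2009,bmi,0,21,Inf,right
bodex-published-2009,bmi,1,-Inf,21,right
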