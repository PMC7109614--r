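source,index,level,lower,upper
copdflow-default-bands,bode,mild,0,3
copdflow-default-bands,bode,moderate,3,5
copdflow-default-bands,bode,severe,5,7
copdflow-default-bands,bode,very_severe,7,11
copdflow-default-bands,bodex,mild,0,3
copdflow-default-bands,bodex,moderate,3,5
copdflow-default-bands,bodex,severe,5,7
copdflow-default-bands,bodex,very_severe,7,10
copdflow-default-bands,fev1_pct,very_severe,0,30
copdflow-default-bands,fev1_pct,severe,30,50
copdflow-default-bands,fev1_pct,moderate,50,80
copdflow-default-bands,fev1_pct,mild,80,Inf
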