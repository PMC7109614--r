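source,level,lower,upper
copdflow-default-bands,low,0,10
copdflow-default-bands,moderate,10,21
copdflow-default-bands,high,21,31
copdflow-default-bands,very_high,31,41
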