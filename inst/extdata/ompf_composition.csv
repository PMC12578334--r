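residue,type,model_pka
E2,GLU,4.25
D97,ASP,3.65
D107,ASP,3.65
D113,ASP,3.65
D121,ASP,3.65
E117,GLU,4.25
D172,ASP,3.65
E233,GLU,4.25
D330,ASP,3.65
D12,ASP,3.65
D21,ASP,3.65
D43,ASP,3.65
D54,ASP,3.65
D74,ASP,3.65
D82,ASP,3.65
D92,ASP,3.65
D137,ASP,3.65
D149,ASP,3.65
D183,ASP,3.65
D195,ASP,3.65
D224,ASP,3.65
D268,ASP,3.65
D283,ASP,3.65
D315,ASP,3.65
E9,GLU,4.25
E29,GLU,4.25
E48,GLU,4.25
E139,GLU,4.25
E244,GLU,4.25
E274,GLU,4.25
E301,GLU,4.25
D37,ASP,3.65
E62,GLU,4.25
E71,GLU,4.25
D126,ASP,3.65
D127,ASP,3.65
D256,ASP,3.65
E296,GLU,4.25
D312,ASP,3.65
D158,ASP,3.65
E181,GLU,4.25
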