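{"kind":"parametric","seed":20260920,"offset":0.3,"ml":[2,4,7,11,16],"condition":[5,10,15,20,25]}
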