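{"true_DI":100,"theta":250,"seed":20260920,"t_ph":0.2,"n_rep":10,"mask":"ellipse"}
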