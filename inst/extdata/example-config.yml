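# example experiment configuration for the contactpred CLI
dialect: sociopatterns_tsv
t0: 0
t1: 172800        # 48 h, prediction time
t2: 216000        # 60 h, testing window end
method: CN,RA
alpha: 1
S: 1
t0_grid: 0, 43200, 86400
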