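{"k0":1,"gamma":0.7,"a":3,"b":0.5,"t_cut":10,"seed":20260,"n_runs":41,"horizon":50,"note":"synthetic ensemble drawn from the time-dependent-rate survival law"}
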