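{"true_breaks":12,"scenario":{"length":20,"n1":3000,"r":2,"k":2000,"delta_r":0,"delta_k":0.75,"tau":0.02},"signs":{"r":-1,"k":-1},"seed":123}
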