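{"m":3,"p":3,"R":[0.12,0.4,0.48,0.054,0.892,0.054,0.034,0.738,0.228],"s":[0.333333333333333,0.333333333333333,0.333333333333333],"d":1,"death_rates":[0,0,0]}
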