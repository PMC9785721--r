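component,1400,1420,1440,1460,1480,1500
melanin,0.9,1,0.95,0.7,0.5,0.4
free_1,,,,,,
free_2,,,,,,
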