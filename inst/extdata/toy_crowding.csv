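reaction,a
RESP,0.13
OVFL,0.006
ACEOX,0.16
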