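[FW]-x(2)-[NQS]-G-x(2,3)-[LIVM]-x-H-C-G-W-[NS]-S
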