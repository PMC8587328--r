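ANY	Male
ANY	Female
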