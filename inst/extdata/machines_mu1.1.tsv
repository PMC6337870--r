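species	count	source
ribosomes	1044	Rudorf and Lipowsky, actively translating ribosomes at growth rate 1.1 per hour, 0.064 um^3
eftu	9122	Rudorf and Lipowsky, EFTu at growth rate 1.1 per hour, 0.064 um^3
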