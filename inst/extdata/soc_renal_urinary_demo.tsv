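pt	scope
Urinary incontinence	soc_renal_urinary
Urinary hesitation	soc_renal_urinary
Kidney enlargement	soc_renal_urinary
Renal tubular necrosis	soc_renal_urinary
Paroxysmal nocturnal haemoglobinuria	soc_renal_urinary
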