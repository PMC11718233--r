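If the evidence is uncertain, decide which explanation of the overall record is the most likely. Answer "yes" if the disease is the most plausible explanation even when some expected findings are missing. Answer "no" if another diagnosis explains the record better, or if the evidence amounts to an isolated diagnosis without support.
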