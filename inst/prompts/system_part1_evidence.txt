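Before giving your answer, first discuss the evidence in the patient profile that argues in favor of the disease, and then discuss the evidence that argues against it.
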