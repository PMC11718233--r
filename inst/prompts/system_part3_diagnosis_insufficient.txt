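Keep in mind that a recorded diagnosis code alone is not sufficient evidence that the patient truly had the disease. Look for corroborating findings such as symptoms, laboratory results, treatments, or complications before concluding that the patient was a true case.
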