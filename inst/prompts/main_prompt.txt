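Below is a structured profile of a patient, extracted from their healthcare records and organized relative to the index date (day 0).

{profile}

Question: Did this patient have {disease_name}, defined as {conceptual_definition}, on the index date (day 0)?
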