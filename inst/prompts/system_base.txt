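You are assisting with the review of patient records extracted from a healthcare database. You will be shown a structured profile of a single patient, organized relative to an index date (day 0). Your task is to determine whether the patient truly had {disease_name} on the index date. Conclude your response with a final section that begins with the word "Summary:" followed by a single word: "yes" if the patient truly had the disease, or "no" if they did not.
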