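therapeutic_class,p_phase1_to_2,p_phase2_to_3,p_phase3_to_rr,p_rr_to_approval,printed_overall_success
Antineoplastic/immunologic,71.8,49,55.3,100,19.4
Cardiovascular,62.9,32.4,64.3,66.7,8.7
CNS,59.6,33,46.4,90,8.2
GI/metabolism,67.5,34.9,50,80,9.4
Musculoskeletal,72.4,35.2,80,100,20.4
Respiratory,72.5,20,85.7,80,9.9
Systemic anti-infective,58.2,52.2,78.6,100,23.9
Miscellaneous,62.8,48.7,69.8,91.3,19.5
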