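chemical,as_printed,rel_ug_m3,cpv_inh,rfc_ug_m3,resolution_note
Cr,0.25100.0083,0.2,510,0.0083,"REL 0.2 / CPV 510 / RfC 0.0083: CPV 510 times the published mean chronic inhalation dose 8.62e-7 reproduces the published Cr cancer risk 4.39e-4; RfC 0.0083 reproduces the Cr hazard quotient magnitude"
Cd,0.0215,0.02,15,,"REL 0.02 / CPV 15: CPV 15 times the mean dose 1.31e-8 reproduces the published Cd cancer risk 1.97e-7; REL 0.02 reproduces the Cd hazard quotient 2.29e-3"
acetaldehyde,1400.0019,140,0.01,9,"REL 140 / CPV 0.01 / RfC 9: only CPV 0.01 (the OEHHA value) times the mean dose 1.57e-3 reproduces the published acetaldehyde cancer risk 1.57e-5; RfC 9 reproduces the hazard quotient 0.609"
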