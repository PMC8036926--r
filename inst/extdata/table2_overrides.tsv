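patient_id	item	grade	note
F1II-4	IGG	0	printed grade departs from presence rule (titre 1200)
F1II-8	IGG	0	printed grade departs from presence rule (titre 1000)
F1II-12	IGG	0	printed grade departs from presence rule (titre 1350)
F2II-1	IGG	0	printed grade departs from presence rule (titre 1000)
F2II-3	IGG	0	printed grade departs from presence rule (titre 1010)
F2II-4	IGG	0	printed grade departs from presence rule (titre 850)
F2II-5	IGG	0	printed grade departs from presence rule (titre 900)
F1II-9	BMI	1	printed grade 1 though BMI 21.4 falls in the normal-weight bin
F2II-5	AAO	3	printed grade 3 though onset 29 falls in the 29-15 bin (grade 4)
F1II-13	MVP	1	printed grade 1 though the clinical table and text report no prolapse
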