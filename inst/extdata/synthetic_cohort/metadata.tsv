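sample_id	patient_id	specimen_type	library_size
P01_plaque	P01	plaque	23339
P01_abscess	P01	abscess	32945
P02_plaque	P02	plaque	17585
P02_abscess	P02	abscess	21070
P03_plaque	P03	plaque	20546
P03_abscess	P03	abscess	25999
P04_plaque	P04	plaque	19518
P04_abscess	P04	abscess	18981
P05_plaque	P05	plaque	15239
P05_abscess	P05	abscess	26342
P06_plaque	P06	plaque	16649
P06_abscess	P06	abscess	31255
P07_plaque	P07	plaque	20920
P07_abscess	P07	abscess	10805
P08_plaque	P08	plaque	30692
P08_abscess	P08	abscess	26313
P09_plaque	P09	plaque	18534
P09_abscess	P09	abscess	21528
P10_plaque	P10	plaque	22896
P10_abscess	P10	abscess	22015
P11_plaque	P11	plaque	19490
P11_abscess	P11	abscess	18950
P12_plaque	P12	plaque	22380
P12_abscess	P12	abscess	15332
blank_01	NA	blank	618
blank_02	NA	blank	722
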