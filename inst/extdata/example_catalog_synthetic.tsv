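name	N	N_H	pf_cm3_s	dG_kcal_mol	quality
synthetic_channel_01	3	0	2.43574895823527e-12	NA	direct_count
synthetic_channel_02	5	3	6.66564324768792e-13	NA	direct_count
synthetic_channel_03	4	6	3.52326391552476e-13	NA	direct_count
synthetic_channel_04	6	9	1.34436380446461e-13	NA	estimated
synthetic_channel_05	8	12	5.818519392036e-14	NA	direct_count
synthetic_channel_06	8	16	1.29209673761393e-14	NA	direct_count
synthetic_channel_07	8	20	3.41161139741074e-15	NA	estimated
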