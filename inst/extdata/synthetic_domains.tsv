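parent_id	domain_name	start_res	end_res
synthetic_lpmo10c	AA10	35	228
synthetic_lpmo10c	CBM2	263	364
synthetic_modular_2	CAT	1	180
synthetic_modular_2	CBM	207	296
synthetic_modular_3	CAT	1	150
synthetic_modular_3	CBM	209	318
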