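"target","fitted","reference","rel_residual"
"mh_tg_pct",2.11183375776196,2.3,-0.0818
"mh_tsyn_ratio_half",1.28477231402942,1.64,-0.2166
"mh_ffa_c",37.5430884303862,21.5,0.7462
"ir_tg_pct",3.04372563118995,5.5,-0.4466
"ir_tg_pct_pc",2.77749824185879,7.4,-0.6247
"naf_tsyn_ratio_half",0.998385633679675,2.34,-0.5733
"naf_tg_ratio_endpoint",1.00062243827351,1.8,-0.4441
"naf_atp_fall_pct",5.2358522097713,19.5,-0.7315
"naf_boxi_rise_pct",41.7362964993348,45,-0.0725
"naf_lgen_fold",2.83339829889936,2.31,0.2266
"naf_tsyn_fold",5.2698706760457,2.05,1.5707
"baseline_glucose_mM",5.02998328740968,5.03,0
"ffaup_minus_tg_ratio",1.5647676315495,2.62,-0.4028
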