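quantity,value
total_scans,6524
main_scans,5890
main_participants,4435
main_procedures,23
ts_scans,634
ts_participants,134
ts_procedures,28
ts_female,49
ts_printed_pct_female,36.6
ts_printed_mean_scans,4.7
ts_printed_sd_scans,2.0
ts_min_scans,2
ts_max_scans,9
bodysize_n,1546
bodysize_height_mean_cm,165.4
bodysize_height_sd_cm,8.8
bodysize_weight_mean_kg,60.1
bodysize_weight_sd_kg,13.6
elderly_n,97
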