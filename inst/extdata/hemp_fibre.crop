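# ideocrop crop parameter file
name = hemp_fibre
t_base_degC = 1.5
t_upper_degC = 40
ccx_frac = 0.94999999999999996
cgc_per_day = 0.11917
cdc_per_day = 0.096149999999999999
zr_min_m = 0.29999999999999999
zr_max_m = 2
d_emergence_das = 10
d_max_root_das = 60
d_flowering_das = 72
d_flowering_length_days = 17
d_hi_buildup_days = 15
d_senescence_das = 105
d_maturity_das = 140
wp_normalized_g_m2 = 18
hi_ref_frac = 1
plant_population_per_ha = 140000
seedling_cover_m2 = 0.00050000000000000001
hi_onset_offset_days = 0
stress_hi_pos_veg = moderate
stress_hi_pos_leaf = moderate
stress_hi_neg_stomatal = strong
stress_aeration = sensitive
stress_p_upper_flowering = NA
stress_p_upper_expansion = 0.20000000000000001
stress_p_lower_expansion = 0.59999999999999998
stress_p_upper_stomatal = 0.34999999999999998
stress_p_upper_senescence = 0.69999999999999996
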