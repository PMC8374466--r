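# ideocrop crop parameter file
name = sugarcane_baseline
t_base_degC = 9
t_upper_degC = 32
ccx_frac = 0.94999999999999996
cgc_per_day = 0.12548000000000001
cdc_per_day = 0.076149999999999995
zr_min_m = 0.29999999999999999
zr_max_m = 1.8
d_emergence_das = 7
d_max_root_das = 60
d_flowering_das = NA
d_flowering_length_days = NA
d_hi_buildup_days = 20
d_senescence_das = 330
d_maturity_das = 365
wp_normalized_g_m2 = 30
hi_ref_frac = 0.34999999999999998
plant_population_per_ha = 140000
seedling_cover_m2 = 0.00050000000000000001
hi_onset_offset_days = 0
stress_hi_pos_veg = moderate
stress_hi_pos_leaf = moderate
stress_hi_neg_stomatal = moderate
stress_aeration = sensitive
stress_p_upper_flowering = NA
stress_p_upper_expansion = 0.20000000000000001
stress_p_lower_expansion = 0.59999999999999998
stress_p_upper_stomatal = 0.5
stress_p_upper_senescence = 0.69999999999999996
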