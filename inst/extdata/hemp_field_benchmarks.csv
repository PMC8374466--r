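block,crop,variable,year,observed_t_ha,simulated_t_ha,reported_rmse_t_ha
calibration,grain,seed_yield,2014,1.8,2.1,0.1
calibration,grain,biomass,2014,7.1,8.3,1.2
calibration,fibre,biomass,2014,11.4,13.3,0.2
validation,grain,seed_yield,2015,2.1,2.2,0.1
validation,grain,biomass,2015,9.8,9.5,0.3
validation,fibre,biomass,2015,12.5,12.3,0.2
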