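stratum,n_facilities,avg_employees,population,exp_human_resources,exp_materials,exp_public_funds
urban,7,134,823809,8337175.71,1038666.67,3380284.76
suburban,10,116,472600,9099476.35,1532670.48,2941083.97
all,17,123,1296408,17436651.90,2571336.98,6321368.73
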