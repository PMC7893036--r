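response,term,estimate,conf_low,conf_high,scale,family,n_obs,n_animals
t_max,intercept,39.84,39.69,39.99,identity,gaussian,2002,11
t_max,season,-0.21,-0.30,-0.12,identity,gaussian,2002,11
t_max,species,0.03,-0.21,0.26,identity,gaussian,2002,11
t_max,interaction,-0.14,-0.27,-0.01,identity,gaussian,2002,11
t_min,intercept,37.64,37.32,37.96,identity,gaussian,2002,11
t_min,season,-0.13,-0.25,-0.01,identity,gaussian,2002,11
t_min,species,-0.97,-1.49,-0.46,identity,gaussian,2002,11
t_min,interaction,0.90,0.71,1.08,identity,gaussian,2002,11
t_amplitude,intercept,2.2,1.93,2.46,identity,gaussian,2002,11
t_amplitude,season,-0.08,-0.21,0.05,identity,gaussian,2002,11
t_amplitude,species,1.0,0.58,1.42,identity,gaussian,2002,11
t_amplitude,interaction,-1.03,-1.21,-0.85,identity,gaussian,2002,11
cumulative_cool_use,intercept,17.38,14.65,20.12,identity,gaussian,1177,10
cumulative_cool_use,season,-8.54,-11.28,-5.79,identity,gaussian,1177,10
cumulative_cool_use,species,2.78,0.11,5.44,identity,gaussian,1177,10
cumulative_cool_use,interaction,-1.45,-2.88,-0.01,identity,gaussian,1177,10
cool_hours,intercept,5.16,4.54,5.86,response-rate,poisson,1168,10
cool_hours,season,0.72,0.61,0.84,response-rate,poisson,1168,10
total_activity_24h,intercept,0.89,0.74,1.04,log,gaussian,1183,8
total_activity_24h,season,-0.07,-0.17,0.03,log,gaussian,1183,8
total_activity_24h,species,-0.13,-0.34,0.07,log,gaussian,1183,8
total_activity_24h,interaction,0.52,0.40,0.64,log,gaussian,1183,8
heat_activity_proportion,intercept,0.13,0.11,0.14,response-proportion,binomial,1183,8
heat_activity_proportion,season,0.05,0.03,0.07,response-proportion,binomial,1183,8
heat_activity_proportion,species,-0.01,-0.03,0.01,response-proportion,binomial,1183,8
heat_activity_proportion,interaction,-0.05,-0.08,-0.03,response-proportion,binomial,1183,8
travel_hours,intercept,0.06,0.04,0.09,response-rate,poisson,1326,10
travel_hours,season,1.57,1.01,2.43,response-rate,poisson,1326,10
travel_hours,species,4.68,3.02,7.27,response-rate,poisson,1326,10
travel_hours,interaction,0.37,0.20,0.69,response-rate,poisson,1326,10
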