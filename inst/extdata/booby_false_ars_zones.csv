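trip_id,trip_duration_h,max_dist_col_km,total_dist_km,ars_duration_h,mean_dist_col_km,scale_km,n_dives,pct_sitting,pct_flight
18.2,2.92,11.0,36.49,0.68,9.18,0.6,0,92.3,7.7
70.2,8.74,15.71,68.53,6.85,14.69,4.0,1,76.4,21.9
70.3,6.57,36.64,113.84,1.41,15.34,0.8,1,71.3,26.3
70.3,6.57,36.64,113.84,1.07,10.28,0.8,0,71.4,26.3
272.1,9.73,65.92,168.74,1.63,56.62,0.4,1,98.3,1.3
275.1,4.87,16.29,121.82,0.46,14.46,0.5,0,94.3,4.6
285.1,7.17,19.38,44.16,6.09,18.81,1.4,5,95.2,3.5
287.1,2.39,16.58,37.62,0.82,11.53,1.4,0,72.3,26.5
287.1,2.39,16.58,37.62,0.40,11.45,1.4,0,83.6,14.3
290.2,2.26,37.77,77.76,0.45,25.13,2.3,2,81.3,17.5
363.3.1,12.19,250.39,275.19,5.27,244.52,3.8,14,80.5,17.7
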