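subject,forecast_error_mean,forecast_error_sd,accuracy_mean,accuracy_sd,dsc,tre_initial,tre_updated
1,0.4,0.3,80.5,10.3,90.2,2.1,1.8
2,0.3,0.3,73.9,19.9,85.3,1.4,0.8
3,0.3,0.2,80.0,13.8,92.6,1.7,0.8
4,0.4,0.2,87.2,27.2,94.5,3.1,0.8
5,0.8,0.7,71.5,15.8,82.8,2.0,1.4
6,0.4,0.5,82.9,18.4,88.5,3.1,0.9
7,0.4,0.2,82.9,10.7,88.5,2.7,1.0
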