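date,sunrise_utc_min,sunset_utc_min
2017-05-01,241.268,1130.272
2017-05-08,229.018,1141.345
2017-05-15,218.155,1151.955
2017-05-22,208.953,1161.818
2017-05-29,201.686,1170.589
2017-06-05,196.598,1177.886
2017-06-12,193.873,1183.332
2017-06-19,193.596,1186.605
2017-06-26,195.726,1187.483
2017-07-03,200.090,1185.875
2017-07-10,206.400,1181.820
2017-07-17,214.296,1175.470
2017-07-24,223.393,1167.052
2017-07-31,233.330,1156.834
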