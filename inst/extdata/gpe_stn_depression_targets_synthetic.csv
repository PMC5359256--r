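"protocol","freq_hz","time_s","value"
"steady_state",1,NA,0.5903
"steady_state",10,NA,0.2647
"steady_state",20,NA,0.2034
"steady_state",33,NA,0.1676
"steady_state",100,NA,0.1086
"recovery",100,0.5,0.2429
"recovery",100,1,0.3591
"recovery",100,2,0.5408
"recovery",100,5,0.8311
"recovery",100,10,0.9681
"recovery",100,20,0.9989
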