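shell,shell_lower,shell_upper,shell_midpoint,profile,sigma_lower,sigma_upper,sigma_mean,A_mean
Small,92.8,101.8,97.3,I,8.5,9.5,9.1,21.6
Small,92.8,101.8,97.3,II,9.3,10.3,9.9,22.8
Small,92.8,101.8,97.3,III,10.1,11.1,10.4,23.2
Medium,100.3,109.4,104.9,I,8.8,9.8,9.3,22.6
Medium,100.3,109.4,104.9,II,9.6,10.6,10.2,24.4
Medium,100.3,109.4,104.9,III,10.5,11.5,10.7,24.2
Large,107.8,116.9,112.4,I,9.3,10.2,9.7,21.7
Large,107.8,116.9,112.4,II,10.0,11.0,10.5,24.2
Large,107.8,116.9,112.4,III,10.8,11.7,11.2,23.8
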