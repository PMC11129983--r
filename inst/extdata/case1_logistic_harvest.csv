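time,observation
0,2.3655799114522011
100,4.2442130690623943
200,21.360214667178646
300,40.230188783340473
400,47.065766250570675
500,70.264693110863504
600,72.141246303174185
700,79.028333576225208
800,75.384453309985417
900,87.095665419045488
1000,80.700563529473627
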