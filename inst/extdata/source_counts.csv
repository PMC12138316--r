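source,time_until,sample_size,fake_count,genuine_count
CTF,~2021,1292,1130,162
FightingInfodemic,~2021,218,62,156
CoAID,~2020,70,0,70
FibVID,~2020,615,318,297
FaCOV,~2021,811,811,0
PolitiFact,~2023,87,42,45
Snopes,~2023,15,9,6
CDC_WHO,~2023,58,0,58
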