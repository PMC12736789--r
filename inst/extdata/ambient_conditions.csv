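# Ambient temperature (deg C) and relative humidity (%) logged during a
# four-participant, three-day pilot of the scripted mask-wearing protocol.
participant,day,temp_c,rh_pct
P1,1,23.7,21.4
P2,1,22.2,31.8
P3,1,23.9,21.2
P4,1,23.0,30.8
P1,2,22.9,51.3
P2,2,22.9,54.5
P3,2,22.3,55.4
P4,2,22.9,50.9
P1,3,22.7,51.3
P2,3,22.7,51.1
P3,3,23.0,50.2
P4,3,22.7,51.5
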