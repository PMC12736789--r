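# Per-wave mean respiration rates (breaths/min) for normal (N) and deep (D)
# breathing, waves 2-6 of the scripted protocol, from a four-participant,
# three-day pilot. Empty cells: wave not available (missed cue).
participant,day,wave,normal_rr,deep_rr
P1,1,2,20.1,7.6
P1,1,3,21.2,7.5
P1,1,4,21.7,7.0
P1,1,5,20.5,6.9
P1,1,6,20.8,8.0
P1,2,2,18.6,7.5
P1,2,3,18.4,8.8
P1,2,4,19.1,8.7
P1,2,5,18.6,7.9
P1,2,6,18.1,7.9
P1,3,2,17.9,7.6
P1,3,3,17.9,8.2
P1,3,4,18.7,9.6
P1,3,5,18.1,8.3
P1,3,6,18.2,10.5
P2,1,2,19.5,5.2
P2,1,3,18.7,4.9
P2,1,4,17.5,5.2
P2,1,5,18.7,4.8
P2,1,6,19.2,5.4
P2,2,2,17.1,8.0
P2,2,3,18.8,8.6
P2,2,4,17.9,7.6
P2,2,5,,
P2,2,6,19.0,5.6
P2,3,2,18.8,4.8
P2,3,3,18.8,5.2
P2,3,4,18.9,4.9
P2,3,5,19.7,10.2
P2,3,6,20.5,6.9
P3,1,2,20.2,11.0
P3,1,3,20.9,13.0
P3,1,4,21.5,14.0
P3,1,5,21.6,13.5
P3,1,6,21.6,19.6
P3,2,2,19.5,10.6
P3,2,3,21.7,13.9
P3,2,4,21.9,15.8
P3,2,5,21.6,12.5
P3,2,6,19.6,12.4
P3,3,2,21.4,12.1
P3,3,3,20.1,11.4
P3,3,4,21.9,13.0
P3,3,5,20.8,13.7
P3,3,6,21.8,13.1
P4,1,2,20.7,10.2
P4,1,3,21.3,11.4
P4,1,4,20.2,10.7
P4,1,5,20.0,11.2
P4,1,6,20.6,12.6
P4,2,2,15.7,9.3
P4,2,3,19.0,9.4
P4,2,4,17.3,9.2
P4,2,5,18.7,8.7
P4,2,6,18.1,8.6
P4,3,2,22.2,12.8
P4,3,3,21.6,11.0
P4,3,4,21.0,9.7
P4,3,5,20.7,8.4
P4,3,6,20.8,8.9
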