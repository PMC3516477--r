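>ABF1_synthetic
# Synthetic Abf1-like count matrix (this is NOT a published Abf1 PWM; it is
# a stand-in built around the field's RTCRYYNNNNNACG Abf1 consensus shape,
# for simulation and testing only).
A [ 45  5 10 55  2 10 25 25 25 25 25 80  5  5 ]
C [  5  5 70  5 48 45 25 25 25 25 25  5 90  5 ]
G [ 40  5 10 35  2 10 25 25 25 25 25 10  2 85 ]
T [ 10 85 10  5 48 35 25 25 25 25 25  5  3  5 ]
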