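3
Lattice="30 0.0 0.0 0.0 30 0.0 0.0 0.0 80" Properties=species:S:1:pos:R:3:id:I:1 Time=0.000000 replicate_id=1 seed=5 fingerprint=hand
ion 0.500000 -1.250000 10.000000 1
water 2.000000 0.000000 -35.000000 2
water -2.000000 1.000000 35.000000 3
3
Lattice="30 0.0 0.0 0.0 30 0.0 0.0 0.0 80" Properties=species:S:1:pos:R:3:id:I:1 Time=50.000000 replicate_id=1 seed=5 fingerprint=hand
ion 0.600000 -1.300000 12.500000 1
water 1.900000 0.100000 -34.000000 2
water -2.100000 0.900000 34.000000 3
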