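id,height_cm,age,recorded_weight_kg
s1,187.7,50,114.0
s2,160.9,50,68.1
s3,170.0,50,135.10
s4,157.7,80,64.60
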