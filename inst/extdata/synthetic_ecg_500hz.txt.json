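{"fs":500,"label":"synthetic 4 s limb-lead ECG, 500 Hz","annotations":[228,696,1157,1610]}
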