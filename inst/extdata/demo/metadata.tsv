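sample	group
control_1	control
control_2	control
control_3	control
restricted_1	restricted
restricted_2	restricted
restricted_3	restricted
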