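u1	v5
u6	v1
u3	v2
u2	v2
u1	v4
u2	v3
u3	v1
u5	v5
u4	v5
u2	v5
u5	v3
u4	v1
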