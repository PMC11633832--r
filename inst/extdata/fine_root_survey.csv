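plant,method,total_fine_root_length_cm,n_fine_roots
1,excavation,640.7,121
2,excavation,689.8,149
3,washout,1776.9,145
4,washout,1449.7,138
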