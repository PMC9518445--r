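bit,field,options
0,channel_mask,Fp2-F4|F4-C4|C4-A1
1,channel_mask,Fp2-F4|F4-C4|C4-A1
2,channel_mask,Fp2-F4|F4-C4|C4-A1
3,time_steps,5|10|15|25
4,time_steps,5|10|15|25
5,n_layers,1|2
6,bidirectional,FALSE|TRUE
7,hidden,50|100|150|200
8,hidden,50|100|150|200
9,dropout,0.05|0.1|0.15|0.2
10,dropout,0.05|0.1|0.15|0.2
11,dense,0|100|200|300
12,dense,0|100|200|300
13,activation,tanh|sigmoid|relu|selu
14,activation,tanh|sigmoid|relu|selu
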