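dp_cmh2o,flow_lpm
0.25,22.6
0.5,31.9
1.0,44.8
1.5,55.3
2.0,63.4
2.5,71.2
3.0,78.1
3.5,84.0
4.0,90.3
4.5,95.2
5.0,100.8
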