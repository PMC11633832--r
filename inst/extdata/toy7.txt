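# toy digitized root system: stem, one adventitious root, one lateral
# soil_ref=1
0 stem -5.000000 0.000000 0.000000
1 stem 0.000000 0.000000 0.000000
2 stem 20.000000 0.000000 0.000000
2.1 root 20.000000 0.000000 0.000000
2.2 root 25.000000 4.000000 3.000000
2.2.1 root 25.000000 4.000000 3.000000
2.2.2 root 33.000000 4.000000 3.000000
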