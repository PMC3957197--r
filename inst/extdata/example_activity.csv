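# start_timestamp=2000-01-01 00:00
# bin_width_min=120
# schedule=0-720:light;720-1440:dark;1440-2160:light;2160-2880:dark
count
1
0
2
1
0
3
55
60
48
52
61
57
2
1
0
1
3
2
49
58
63
50
47
59
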