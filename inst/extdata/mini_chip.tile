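platform: mini-chip
rows: 5
cols: 4
tile_x: 1000
tile_y: 1000
0 0 1
0 1 2
0 2 3
0 3 4
1 0 5
1 1 6
1 2 7
1 3 8
2 0 9
2 1 10
2 2 11
2 3 12
3 0 13
3 1 14
3 2 15
3 3 16
4 0 17
4 1 18
4 2 19
4 3 20
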