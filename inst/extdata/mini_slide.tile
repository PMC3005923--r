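platform: mini-slide
rows: 6
cols: 10
tile_x: 500
tile_y: 500
0 0 1 unused
0 1 2
0 2 3
0 3 4
0 4 5
0 5 6
0 6 7
0 7 8
0 8 9
0 9 10 unused
1 0 11
1 1 12
1 2 13
1 3 14
1 4 15
1 5 16
1 6 17
1 7 18
1 8 19
1 9 20
2 0 21
2 1 22
2 2 23
2 3 24
2 4 25
2 5 26
2 6 27
2 7 28
2 8 29
2 9 30
3 0 31
3 1 32
3 2 33
3 3 34
3 4 35
3 5 36
3 6 37
3 7 38
3 8 39
3 9 40
4 0 41
4 1 42
4 2 43
4 3 44
4 4 45
4 5 46
4 6 47
4 7 48
4 8 49
4 9 50
5 0 51 unused
5 1 52
5 2 53
5 3 54
5 4 55
5 5 56
5 6 57
5 7 58
5 8 59
5 9 60 unused
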