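42
0.27256 0.25771 0.24967 0.22006
 0.058  0.058  0.058  0.826
 0.058  0.058  0.058  0.826
 0.826  0.058  0.058  0.058
0.1715 0.26997 0.30599 0.25254
43
0.27256 0.25771 0.24967 0.22006
 0.058  0.058  0.058  0.826
 0.058  0.058  0.058  0.826
 0.826  0.058  0.058  0.058
0.1715 0.26997 0.30599 0.25254
44
0.27256 0.25771 0.24967 0.22006
 0.058  0.058  0.058  0.826
 0.058  0.058  0.058  0.826
 0.826  0.058  0.058  0.058
0.1715 0.26997 0.30599 0.25254
45
0.27256 0.25771 0.24967 0.22006
 0.058  0.058  0.058  0.826
 0.058  0.058  0.058  0.826
 0.826  0.058  0.058  0.058
0.1715 0.26997 0.30599 0.25254
46
0.27256 0.25771 0.24967 0.22006
 0.058  0.058  0.058  0.826
 0.058  0.058  0.058  0.826
 0.826  0.058  0.058  0.058
0.1715 0.26997 0.30599 0.25254
47
0.27256 0.25771 0.24967 0.22006
 0.058  0.058  0.058  0.826
 0.058  0.058  0.058  0.826
 0.826  0.058  0.058  0.058
0.1715 0.26997 0.30599 0.25254
48
0.27256 0.25771 0.24967 0.22006
 0.058  0.058  0.058  0.826
 0.058  0.058  0.058  0.826
 0.826  0.058  0.058  0.058
0.1715 0.26997 0.30599 0.25254
49
0.27256 0.25771 0.24967 0.22006
 0.058  0.058  0.058  0.826
 0.058  0.058  0.058  0.826
 0.826  0.058  0.058  0.058
0.1715 0.26997 0.30599 0.25254
50
0.27256 0.25771 0.24967 0.22006
 0.058  0.058  0.058  0.826
 0.058  0.058  0.058  0.826
 0.826  0.058  0.058  0.058
0.1715 0.26997 0.30599 0.25254
51
0.27256 0.25771 0.24967 0.22006
 0.058  0.058  0.058  0.826
 0.058  0.058  0.058  0.826
 0.826  0.058  0.058  0.058
0.1715 0.26997 0.30599 0.25254
52
0.27256 0.25771 0.24967 0.22006
 0.058  0.058  0.058  0.826
 0.058  0.058  0.058  0.826
 0.826  0.058  0.058  0.058
0.1715 0.26997 0.30599 0.25254
53
0.27256 0.25771 0.24967 0.22006
 0.058  0.058  0.058  0.826
 0.058  0.058  0.058  0.826
 0.826  0.058  0.058  0.058
0.1715 0.26997 0.30599 0.25254
54
0.27256 0.25771 0.24967 0.22006
 0.058  0.058  0.058  0.826
 0.058  0.058  0.058  0.826
 0.826  0.058  0.058  0.058
0.1715 0.26997 0.30599 0.25254
55
0.27256 0.25771 0.24967 0.22006
 0.058  0.058  0.058  0.826
 0.058  0.058  0.058  0.826
 0.826  0.058  0.058  0.058
0.1715 0.26997 0.30599 0.25254
56
0.27256 0.25771 0.24967 0.22006
 0.058  0.058  0.058  0.826
 0.058  0.058  0.058  0.826
 0.826  0.058  0.058  0.058
0.1715 0.26997 0.30599 0.25254
57
0.27256 0.25771 0.24967 0.22006
 0.058  0.058  0.058  0.826
 0.058  0.058  0.058  0.826
 0.826  0.058  0.058  0.058
0.1715 0.26997 0.30599 0.25254
58
0.27256 0.25771 0.24967 0.22006
 0.058  0.058  0.058  0.826
 0.058  0.058  0.058  0.826
 0.826  0.058  0.058  0.058
0.1715 0.26997 0.30599 0.25254
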