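42
0.25254 0.30599 0.26997 0.1715
 0.058  0.058  0.058  0.826
 0.826  0.058  0.058  0.058
 0.826  0.058  0.058  0.058
0.22006 0.24967 0.25771 0.27256
43
0.25254 0.30599 0.26997 0.1715
 0.058  0.058  0.058  0.826
 0.826  0.058  0.058  0.058
 0.826  0.058  0.058  0.058
0.22006 0.24967 0.25771 0.27256
44
0.25254 0.30599 0.26997 0.1715
 0.058  0.058  0.058  0.826
 0.826  0.058  0.058  0.058
 0.826  0.058  0.058  0.058
0.22006 0.24967 0.25771 0.27256
45
0.25254 0.30599 0.26997 0.1715
 0.058  0.058  0.058  0.826
 0.826  0.058  0.058  0.058
 0.826  0.058  0.058  0.058
0.22006 0.24967 0.25771 0.27256
46
0.25254 0.30599 0.26997 0.1715
 0.058  0.058  0.058  0.826
 0.826  0.058  0.058  0.058
 0.826  0.058  0.058  0.058
0.22006 0.24967 0.25771 0.27256
47
0.25254 0.30599 0.26997 0.1715
 0.058  0.058  0.058  0.826
 0.826  0.058  0.058  0.058
 0.826  0.058  0.058  0.058
0.22006 0.24967 0.25771 0.27256
48
0.25254 0.30599 0.26997 0.1715
 0.058  0.058  0.058  0.826
 0.826  0.058  0.058  0.058
 0.826  0.058  0.058  0.058
0.22006 0.24967 0.25771 0.27256
49
0.25254 0.30599 0.26997 0.1715
 0.058  0.058  0.058  0.826
 0.826  0.058  0.058  0.058
 0.826  0.058  0.058  0.058
0.22006 0.24967 0.25771 0.27256
50
0.25254 0.30599 0.26997 0.1715
 0.058  0.058  0.058  0.826
 0.826  0.058  0.058  0.058
 0.826  0.058  0.058  0.058
0.22006 0.24967 0.25771 0.27256
51
0.25254 0.30599 0.26997 0.1715
 0.058  0.058  0.058  0.826
 0.826  0.058  0.058  0.058
 0.826  0.058  0.058  0.058
0.22006 0.24967 0.25771 0.27256
52
0.25254 0.30599 0.26997 0.1715
 0.058  0.058  0.058  0.826
 0.826  0.058  0.058  0.058
 0.826  0.058  0.058  0.058
0.22006 0.24967 0.25771 0.27256
53
0.25254 0.30599 0.26997 0.1715
 0.058  0.058  0.058  0.826
 0.826  0.058  0.058  0.058
 0.826  0.058  0.058  0.058
0.22006 0.24967 0.25771 0.27256
54
0.25254 0.30599 0.26997 0.1715
 0.058  0.058  0.058  0.826
 0.826  0.058  0.058  0.058
 0.826  0.058  0.058  0.058
0.22006 0.24967 0.25771 0.27256
55
0.25254 0.30599 0.26997 0.1715
 0.058  0.058  0.058  0.826
 0.826  0.058  0.058  0.058
 0.826  0.058  0.058  0.058
0.22006 0.24967 0.25771 0.27256
56
0.25254 0.30599 0.26997 0.1715
 0.058  0.058  0.058  0.826
 0.826  0.058  0.058  0.058
 0.826  0.058  0.058  0.058
0.22006 0.24967 0.25771 0.27256
57
0.25254 0.30599 0.26997 0.1715
 0.058  0.058  0.058  0.826
 0.826  0.058  0.058  0.058
 0.826  0.058  0.058  0.058
0.22006 0.24967 0.25771 0.27256
58
0.25254 0.30599 0.26997 0.1715
 0.058  0.058  0.058  0.826
 0.826  0.058  0.058  0.058
 0.826  0.058  0.058  0.058
0.22006 0.24967 0.25771 0.27256
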