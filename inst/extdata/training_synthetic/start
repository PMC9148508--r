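42
0.2615 0.23701  0.253 0.24848
 0.826  0.058  0.058  0.058
 0.058  0.058  0.058  0.826
 0.058  0.058  0.826  0.058
0.21699 0.25344 0.29151 0.23806
43
0.2615 0.23701  0.253 0.24848
 0.826  0.058  0.058  0.058
 0.058  0.058  0.058  0.826
 0.058  0.058  0.826  0.058
0.21699 0.25344 0.29151 0.23806
44
0.2615 0.23701  0.253 0.24848
 0.826  0.058  0.058  0.058
 0.058  0.058  0.058  0.826
 0.058  0.058  0.826  0.058
0.21699 0.25344 0.29151 0.23806
45
0.2615 0.23701  0.253 0.24848
 0.826  0.058  0.058  0.058
 0.058  0.058  0.058  0.826
 0.058  0.058  0.826  0.058
0.21699 0.25344 0.29151 0.23806
46
0.2615 0.23701  0.253 0.24848
 0.826  0.058  0.058  0.058
 0.058  0.058  0.058  0.826
 0.058  0.058  0.826  0.058
0.21699 0.25344 0.29151 0.23806
47
0.2615 0.23701  0.253 0.24848
 0.826  0.058  0.058  0.058
 0.058  0.058  0.058  0.826
 0.058  0.058  0.826  0.058
0.21699 0.25344 0.29151 0.23806
48
0.2615 0.23701  0.253 0.24848
 0.826  0.058  0.058  0.058
 0.058  0.058  0.058  0.826
 0.058  0.058  0.826  0.058
0.21699 0.25344 0.29151 0.23806
49
0.2615 0.23701  0.253 0.24848
 0.826  0.058  0.058  0.058
 0.058  0.058  0.058  0.826
 0.058  0.058  0.826  0.058
0.21699 0.25344 0.29151 0.23806
50
0.2615 0.23701  0.253 0.24848
 0.826  0.058  0.058  0.058
 0.058  0.058  0.058  0.826
 0.058  0.058  0.826  0.058
0.21699 0.25344 0.29151 0.23806
51
0.2615 0.23701  0.253 0.24848
 0.826  0.058  0.058  0.058
 0.058  0.058  0.058  0.826
 0.058  0.058  0.826  0.058
0.21699 0.25344 0.29151 0.23806
52
0.2615 0.23701  0.253 0.24848
 0.826  0.058  0.058  0.058
 0.058  0.058  0.058  0.826
 0.058  0.058  0.826  0.058
0.21699 0.25344 0.29151 0.23806
53
0.2615 0.23701  0.253 0.24848
 0.826  0.058  0.058  0.058
 0.058  0.058  0.058  0.826
 0.058  0.058  0.826  0.058
0.21699 0.25344 0.29151 0.23806
54
0.2615 0.23701  0.253 0.24848
 0.826  0.058  0.058  0.058
 0.058  0.058  0.058  0.826
 0.058  0.058  0.826  0.058
0.21699 0.25344 0.29151 0.23806
55
0.2615 0.23701  0.253 0.24848
 0.826  0.058  0.058  0.058
 0.058  0.058  0.058  0.826
 0.058  0.058  0.826  0.058
0.21699 0.25344 0.29151 0.23806
56
0.2615 0.23701  0.253 0.24848
 0.826  0.058  0.058  0.058
 0.058  0.058  0.058  0.826
 0.058  0.058  0.826  0.058
0.21699 0.25344 0.29151 0.23806
57
0.2615 0.23701  0.253 0.24848
 0.826  0.058  0.058  0.058
 0.058  0.058  0.058  0.826
 0.058  0.058  0.826  0.058
0.21699 0.25344 0.29151 0.23806
58
0.2615 0.23701  0.253 0.24848
 0.826  0.058  0.058  0.058
 0.058  0.058  0.058  0.826
 0.058  0.058  0.826  0.058
0.21699 0.25344 0.29151 0.23806
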