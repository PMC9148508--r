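42
0.23806 0.29151 0.25344 0.21699
 0.058  0.826  0.058  0.058
 0.826  0.058  0.058  0.058
 0.058  0.058  0.058  0.826
0.24848  0.253 0.23701 0.2615
43
0.23806 0.29151 0.25344 0.21699
 0.058  0.826  0.058  0.058
 0.826  0.058  0.058  0.058
 0.058  0.058  0.058  0.826
0.24848  0.253 0.23701 0.2615
44
0.23806 0.29151 0.25344 0.21699
 0.058  0.826  0.058  0.058
 0.826  0.058  0.058  0.058
 0.058  0.058  0.058  0.826
0.24848  0.253 0.23701 0.2615
45
0.23806 0.29151 0.25344 0.21699
 0.058  0.826  0.058  0.058
 0.826  0.058  0.058  0.058
 0.058  0.058  0.058  0.826
0.24848  0.253 0.23701 0.2615
46
0.23806 0.29151 0.25344 0.21699
 0.058  0.826  0.058  0.058
 0.826  0.058  0.058  0.058
 0.058  0.058  0.058  0.826
0.24848  0.253 0.23701 0.2615
47
0.23806 0.29151 0.25344 0.21699
 0.058  0.826  0.058  0.058
 0.826  0.058  0.058  0.058
 0.058  0.058  0.058  0.826
0.24848  0.253 0.23701 0.2615
48
0.23806 0.29151 0.25344 0.21699
 0.058  0.826  0.058  0.058
 0.826  0.058  0.058  0.058
 0.058  0.058  0.058  0.826
0.24848  0.253 0.23701 0.2615
49
0.23806 0.29151 0.25344 0.21699
 0.058  0.826  0.058  0.058
 0.826  0.058  0.058  0.058
 0.058  0.058  0.058  0.826
0.24848  0.253 0.23701 0.2615
50
0.23806 0.29151 0.25344 0.21699
 0.058  0.826  0.058  0.058
 0.826  0.058  0.058  0.058
 0.058  0.058  0.058  0.826
0.24848  0.253 0.23701 0.2615
51
0.23806 0.29151 0.25344 0.21699
 0.058  0.826  0.058  0.058
 0.826  0.058  0.058  0.058
 0.058  0.058  0.058  0.826
0.24848  0.253 0.23701 0.2615
52
0.23806 0.29151 0.25344 0.21699
 0.058  0.826  0.058  0.058
 0.826  0.058  0.058  0.058
 0.058  0.058  0.058  0.826
0.24848  0.253 0.23701 0.2615
53
0.23806 0.29151 0.25344 0.21699
 0.058  0.826  0.058  0.058
 0.826  0.058  0.058  0.058
 0.058  0.058  0.058  0.826
0.24848  0.253 0.23701 0.2615
54
0.23806 0.29151 0.25344 0.21699
 0.058  0.826  0.058  0.058
 0.826  0.058  0.058  0.058
 0.058  0.058  0.058  0.826
0.24848  0.253 0.23701 0.2615
55
0.23806 0.29151 0.25344 0.21699
 0.058  0.826  0.058  0.058
 0.826  0.058  0.058  0.058
 0.058  0.058  0.058  0.826
0.24848  0.253 0.23701 0.2615
56
0.23806 0.29151 0.25344 0.21699
 0.058  0.826  0.058  0.058
 0.826  0.058  0.058  0.058
 0.058  0.058  0.058  0.826
0.24848  0.253 0.23701 0.2615
57
0.23806 0.29151 0.25344 0.21699
 0.058  0.826  0.058  0.058
 0.826  0.058  0.058  0.058
 0.058  0.058  0.058  0.826
0.24848  0.253 0.23701 0.2615
58
0.23806 0.29151 0.25344 0.21699
 0.058  0.826  0.058  0.058
 0.826  0.058  0.058  0.058
 0.058  0.058  0.058  0.826
0.24848  0.253 0.23701 0.2615
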