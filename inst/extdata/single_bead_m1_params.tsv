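# One-bead-per-residue force-field parameters, version m1-1.0
# sigma: bead diameter (nm); lambda: stickiness in [0,1], "M1" optimized set;
# charge: elementary charges at neutral pH (His is set at run time from pH);
# mass: residue mass (g/mol).
letter	sigma	lambda	charge	mass
A	0.504	0.2743297	0	71.07
R	0.656	0.7307624	1	156.19
N	0.568	0.4255859	0	114.10
D	0.558	0.0416073	-1	115.09
C	0.548	0.5615435	0	103.14
Q	0.602	0.3934318	0	128.13
E	0.592	0.0006935	-1	129.12
G	0.450	0.7058843	0	57.05
H	0.608	0.4663667	0	137.14
I	0.618	0.5423623	0	113.16
L	0.618	0.6440005	0	113.16
K	0.636	0.1790211	1	128.17
M	0.618	0.5308481	0	131.19
F	0.636	0.8672358	0	147.18
P	0.556	0.3593126	0	97.12
S	0.518	0.4625416	0	87.08
T	0.562	0.3713162	0	101.10
W	0.678	0.9893764	0	186.21
V	0.586	0.2083769	0	99.13
Y	0.646	0.9774611	0	163.18
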