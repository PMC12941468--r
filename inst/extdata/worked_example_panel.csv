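no,species,L_mm,B_mm,area_cm2,dry_weight_g,carbon_g
1,bivalve,25.62,21.94,4.4147,5.4586,0.6627
2,barnacle,6.49,5.52,0.2814,0.0208,0.0025
3,barnacle,4.86,4.03,0.1538,0.0079,0.0009
4,barnacle,4.48,3.98,0.1400,0.0068,0.0008
5,barnacle,3.98,3.58,0.1119,0.0047,0.0006
6,bivalve,7.51,6.72,0.3964,0.0118,0.0014
7,barnacle,4.86,4.25,0.1622,0.0086,0.0010
8,barnacle,3.75,3.36,0.0990,0.0039,0.0005
9,barnacle,2.87,2.91,0.0656,0.0020,0.0002
10,barnacle,3.09,2.91,0.0706,0.0022,0.0003
11,barnacle,9.63,7.07,0.5347,0.0584,0.0070
12,barnacle,5.74,4.03,0.1817,0.0103,0.0012
13,bivalve,7.95,6.05,0.3778,0.0104,0.0013
14,barnacle,3.58,3.09,0.0869,0.0031,0.0004
15,barnacle,3.53,2.69,0.0746,0.0025,0.0003
16,barnacle,4.86,4.03,0.1538,0.0079,0.0009
17,barnacle,3.75,3.13,0.0922,0.0035,0.0004
18,barnacle,6.49,3.31,0.1687,0.0091,0.0011
19,barnacle,4.64,4.48,0.1633,0.0087,0.0010
20,barnacle,3.09,2.69,0.0653,0.0020,0.0002
21,barnacle,3.75,3.13,0.0922,0.0035,0.0004
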