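# Biological hydrophobicity scale, full model parameterization (v1).
# Position-specific contribution of residue `aa` at 0-based position i of a
# segment of length L:
#   x = 9 * (2*i/(L-1) - 1)                      # normalized coordinate, -9..9
#   dg(aa, x) = c0 * exp(-c1 * x^2)
#             [+ c2 * (exp(-c3*(x - c4)^2) + exp(-c3*(x + c4)^2))]   # W, Y only
# Segment score:
#   dG_app = sum_i dg(aa_i, x_i)
#          + moment_c0 * sqrt((sum_i dg_i sin(a*i))^2 + (sum_i dg_i cos(a*i))^2)
#          + len_c2*L^2 + len_c1*L + len_c0
# with a = 100 degrees per residue (alpha-helical periodicity).
# kcal/mol throughout.  Negative dG_app favors membrane insertion.
profile	A	0.1267255	0.0215152
profile	C	-0.0765051	0.0994228
profile	D	1.7939795	0.0172643
profile	E	1.4193720	0.0089351
profile	F	-0.2766953	0.0010297
profile	G	0.4813492	0.0047210
profile	H	1.1998590	0.0080127
profile	I	-0.4597384	0.0181495
profile	K	1.8485768	0.0218446
profile	L	-0.4077991	0.0403902
profile	M	-0.0774786	0.0434943
profile	N	1.3266132	0.0092375
profile	P	1.0860888	0.0100568
profile	Q	1.3336109	0.0111996
profile	R	1.6492534	0.0512044
profile	S	0.7023921	0.0077661
profile	T	0.5266550	0.0311973
profile	V	-0.2447218	0.0979201
profile	W	0.2909390	0.0189282	-0.5479140	0.0930222	6.4736619
profile	Y	0.6275249	0.0103896	-0.5744404	0.0947821	6.9164963
moment	0.27045	100
length	0.50193	-4.419e-2	9.29e-4
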