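# Loop destabilization free energies for DNA secondary structure at 37 C,
# kcal/mol, after SantaLucia & Hicks (2004), Table 4 (values interpolated
# onto a common size grid; sizes between grid points are interpolated
# linearly and sizes beyond 30 are extrapolated with the Jacobson-Stockmayer
# 1.75*R*T*ln(n/30) term). Multiloop terms are an affine penalty
# a + b*(branches) + c*(unpaired), a coarse standard choice.
type	size	dg37
hairpin	3	3.5
hairpin	4	3.5
hairpin	5	3.3
hairpin	6	4.0
hairpin	7	4.2
hairpin	8	4.3
hairpin	9	4.5
hairpin	10	4.6
hairpin	12	5.0
hairpin	14	5.1
hairpin	16	5.3
hairpin	18	5.5
hairpin	20	5.7
hairpin	25	6.1
hairpin	30	6.3
bulge	1	4.0
bulge	2	2.9
bulge	3	3.1
bulge	4	3.2
bulge	5	3.3
bulge	6	3.5
bulge	7	3.7
bulge	8	3.9
bulge	9	4.1
bulge	10	4.3
bulge	12	4.5
bulge	14	4.8
bulge	16	5.0
bulge	18	5.2
bulge	20	5.3
bulge	25	5.6
bulge	30	5.9
internal	2	4.3
internal	3	3.2
internal	4	3.6
internal	5	4.0
internal	6	4.4
internal	7	4.6
internal	8	4.8
internal	9	4.9
internal	10	4.9
internal	12	5.2
internal	14	5.4
internal	16	5.6
internal	18	5.8
internal	20	5.9
internal	25	6.3
internal	30	6.6
multiloop_offset	0	3.4
multiloop_branch	0	0.4
multiloop_unpaired	0	0.1
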