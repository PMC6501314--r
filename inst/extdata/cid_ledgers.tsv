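unknown_id	faure_name	ion	mz
N1	U^(4Me)2X	precursor	616.0
N1	U^(4Me)2X	Y2	426.0
N1	U^(4Me)2X	Y1	294.1
N1	U^(4Me)2X	0,2X1	523.9
N1	U^(4Me)2X	V3	539.9
N3	U^(4Me)2XX	precursor	748.1
N3	U^(4Me)2XX	0,2X2	655.9
N3	U^(4Me)2XX	E2	461.0
N3	U^(4Me)2XX	V4	671.9
N4	A^3X	precursor	558.1
N4	A^3X	Y1	294.1
N4	A^3X	0,2X1	336.1
N4	A^3X	E2	271.1
N4	A^3X	G3	510.7
N5	XA^3X	precursor	690.1
N5	XA^3X	0,2X1	336.1
N5	XA^3X	E2	403.1
N5	XA^3X	W2	424.1
N5	XA^3X	G3a	642.0
N6	A^3A^3X	precursor	822.0
N6	A^3A^3X	G	773.9
N6	A^3A^3X	W2	424.1
N6	A^3A^3X	G3	656.0
N6	A^3A^3X	E2	271.1
N7	A^3XXX	precursor	822.0
N7	A^3XXX	Y2	426.1
N7	A^3XXX	1,5X2	454.0
N7	A^3XXX	0,2X2	468.1
N7	A^3XXX	G	773.9
N8	D^2,3XX	precursor	822.0
N8	D^2,3XX	Y2	426.1
N8	D^2,3XX	1,5X2	454.0
N8	D^2,3XX	0,2X2	468.1
N8	D^2,3XX	G	773.9
N9	XA^3A^3X	precursor	954.3
N9	XA^3A^3X	1,5X1	322.1
N9	XA^3A^3X	Y1	294.2
N9	XA^3A^3X	G2	392.2
N9	XA^3A^3X	G3	656.1
N9	XA^3A^3X	G3a/G4b	906.4
N10	A^3U^(4Me)2XX	precursor	1012.8
N10	A^3U^(4Me)2XX	Y1	294.3
N10	A^3U^(4Me)2XX	Y2	426.3
N10	A^3U^(4Me)2XX	E3	403.4
N10	A^3U^(4Me)2XX	H3	435.3
N10	A^3U^(4Me)2XX	V3a	936.3
N10	A^3U^(4Me)2XX	Y3	748.3
N10	A^3U^(4Me)2XX	Y4	880.2
N10	A^3U^(4Me)2XX	G4	846.3
N11	D^2,3U^(4Me)2XX	precursor	1144.8
N11	D^2,3U^(4Me)2XX	Y1	294.3
N11	D^2,3U^(4Me)2XX	Y2	426.3
N11	D^2,3U^(4Me)2XX	E4	535.4
N11	D^2,3U^(4Me)2XX	H4	567.3
N11	D^2,3U^(4Me)2XX	G3	714.3
N11	D^2,3U^(4Me)2XX	V3a	1068.3
N11	D^2,3U^(4Me)2XX	Y4	880.2
N11	D^2,3U^(4Me)2XX	Y5	1012.2
N11	D^2,3U^(4Me)2XX	G4	846.3
N11	D^2,3U^(4Me)2XX	0,2X4	1054.3
N12	XA^3XU^(4Me)2XX	precursor	1276.9
N12	XA^3XU^(4Me)2XX	Y1	294.4
N12	XA^3XU^(4Me)2XX	Y2	426.4
N12	XA^3XU^(4Me)2XX	Y3	748.3
N12	XA^3XU^(4Me)2XX	Y4	880.3
N12	XA^3XU^(4Me)2XX	Y5	1144.2
N12	XA^3XU^(4Me)2XX	H3	699.4
N12	XA^3XU^(4Me)2XX	G5	978.3
N12	XA^3XU^(4Me)2XX	V3a	1200.4
M1	D^2,3X	precursor	690.0
M1	D^2,3X	Y1	294.3
M1	D^2,3X	Y2	426.3
M1	D^2,3X	Y3	558.3
M1	D^2,3X	1,4X2	454.3
M1	D^2,3X	1,5X3	586.3
M1	D^2,3X	G3	642.4
M1	D^2,3X	G4	656.5
M1	D^2,3X	0,2X2	600.3
M2	XD^2,3XX	precursor	954.5
M2	XD^2,3XX	Y1	294.4
M2	XD^2,3XX	1,5X1	322.4
M2	XD^2,3XX	Y2	426.4
M2	XD^2,3XX	Y3	690.4
M2	XD^2,3XX	G3	524.5
M2	XD^2,3XX	W3	556.4
M2	XD^2,3XX	D2	271.4
M2	XD^2,3XX	G4	906.5
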