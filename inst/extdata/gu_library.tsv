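name	faure_name	alt_name	unknown_id	gu	gh10_product	gh11_product
U^(4Me)2X	U^(4Me)2X	NA	N1	0.72	TRUE	FALSE
X1	X	NA	NA	0.80	TRUE	TRUE
U^2XX	U^2XX	NA	N2	1.40	TRUE	FALSE
U^(4Me)2XX	U^(4Me)2XX	NA	N3	1.48	TRUE	TRUE
X2	XX	NA	NA	1.57	TRUE	TRUE
XU^2XX	XU^2XX	NA	NA	2.03	FALSE	TRUE
XU^(4Me)2XX	XU^(4Me)2XX	NA	NA	2.07	FALSE	TRUE
X3	XXX	NA	NA	2.24	TRUE	TRUE
A^3X	A^3X	NA	N4	2.31	TRUE	FALSE
A^3U^(4Me)2XX	A^3U^(4Me)2XX	NA	N10	2.74	FALSE	TRUE
XA^3X	XA^3X	NA	N5	2.87	TRUE	TRUE
D^2,3U^(4Me)2XX	D^2,3U^(4Me)2XX	B^2,3U^(4Me)2XX	N11	3.09	FALSE	TRUE
D^2,3X	D^2,3X	NA	M1	3.12	TRUE	FALSE
X4	XXXX	NA	NA	3.17	FALSE	TRUE
A^3A^3X	A^3A^3X	NA	N6	3.70	TRUE	FALSE
A^3XXX	A^3XXX	NA	N7	3.85	TRUE	FALSE
XA^3XX	XA^3XX	NA	NA	3.92	FALSE	TRUE
D^2,3XX	D^2,3XX	NA	N8	3.97	TRUE	FALSE
XA^3XU^(4Me)2XX	XA^3XU^(4Me)2XX	NA	N12	4.01	FALSE	TRUE
X5	XXXXX	NA	NA	4.32	FALSE	FALSE
XA^3A^3X	XA^3A^3X	NA	N9	4.47	TRUE	FALSE
XD^2,3XX	XD^2,3XX	NA	M2	4.83	FALSE	TRUE
X6	XXXXXX	NA	NA	5.54	FALSE	FALSE
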