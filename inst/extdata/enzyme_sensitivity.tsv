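faure_name	unknown_id	gh10_level	gh11_level	CgGH3	GH51	GH62	GH67	GH115
U^(4Me)2X	N1	major	minor	-	-	-	-	+
U^2XX	N2	minor	none	-	-	-	+	+
U^(4Me)2XX	N3	major	minor	-	-	-	+	+
A^3X	N4	major	none	-	+	+	NT	-
XU^2XX	NA	none	minor	-	-	-	+	+
XU^(4Me)2XX	NA	none	minor	-	-	-	+	+
XA^3X	N5	major	major	NT	+	+	NT	-
A^3A^3X	N6	minor	none	NT	+	-	NT	-
A^3XXX	N7	minor	none	NT	+	+	NT	NT
XA^3XX	NA	none	major	-	NT	+	NT	-
D^2,3XX	N8	minor	none	+	-	-	NT	-
XA^3A^3X	N9	minor	none	-	+	-	NT	NT
A^3U^(4Me)2XX	N10	none	minor	NT	+	-	NT	-
D^2,3U^(4Me)2XX	N11	none	minor	-	-	NT	NT	-
XA^3XU^(4Me)2XX	N12	none	minor	NT	+	+	NT	+
D^2,3X	M1	minor	none	+	-	-	-	-
XD^2,3XX	M2	none	minor	+	-	-	-	-
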