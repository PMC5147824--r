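# Published panel of subjects with abnormal semantic-fluency z-scores:
# 9 full-effort controls, 15 simulated malingerers, and 2 TBI patients.
# Sign columns give the control-distribution tail (0.05 or 0.10) at which
# the measure was flagged; empty = not flagged.  n_soi = 1 when the SOI lay
# within one standard deviation of the normative mean.  mi_printed is the
# published malingering-index total.
subject_id	group	z	syll	lwf	typ	tdp	pct_repeat	n_soi	mi_printed
Sub1	control	-2.50	0.05	0.05	0.05			0	3
Sub2	control	-2.48	0.05	0.05		0.05	0.05	0	2
Sub3	control	-2.17			0.05	0.05		0	0
Sub4	control	-2.11						0	0
Sub5	control	-2.11		0.05	0.05	0.05		0	1
Sub6	control	-1.99				0.05		1	0
Sub7	control	-1.94				0.05		0	-1
Sub8	control	-1.75			0.05	0.05	0.05	0	1
Sub9	control	-1.72				0.10	0.10	0	0
mal1	malingerer	-3.02	0.05	0.05			0.05	0	3
mal2	malingerer	-2.96	0.05	0.05	0.05		0.05	0	4
mal3	malingerer	-2.53	0.05	0.05	0.05		0.05	0	4
mal4	malingerer	-2.21	0.10	0.05	0.05		0.10	0	4
mal5	malingerer	-2.17	0.05	0.05	0.05		0.10	1	5
mal6	malingerer	-2.14		0.05	0.05	0.10	0.10	0	2
mal7	malingerer	-2.13	0.05	0.05	0.05		0.10	0	4
mal8	malingerer	-2.04		0.05				0	1
mal9	malingerer	-2.00	0.05	0.05	0.05		0.10	1	5
mal10	malingerer	-1.93	0.05	0.05	0.05		0.05	0	4
mal11	malingerer	-1.92		0.05	0.05		0.05	1	4
mal12	malingerer	-1.89	0.05	0.05	0.10		0.05	1	5
mal13	malingerer	-1.89	0.05	0.05	0.10		0.05	0	4
mal14	malingerer	-1.89			0.05	0.10		1	1
mal15	malingerer	-1.69	0.05	0.05			0.05	1	4
mTBI1	mtbi	-2.23		0.05	0.05	0.10		0	1
sTBI1	stbi	-2.47			0.05	0.05	0.05	0	1
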