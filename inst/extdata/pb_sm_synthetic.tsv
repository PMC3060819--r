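	a	b	c	d	e	f	g	h	i	j	k	l	m	n	o	p
a	5.00	-1.78	-0.33	-1.09	-2.61	-2.09	-1.40	-3.18	-2.54	-2.85	-3.31	-2.26	-2.69	-3.37	-2.59	-1.85
b	-1.78	5.00	-0.16	0.65	-1.31	-1.33	-1.90	-1.76	0.31	-1.74	0.11	-1.31	-2.59	-3.36	-2.55	-1.32
c	-0.33	-0.16	5.00	0.86	-1.13	-0.56	-0.40	-1.94	-1.88	-1.67	-2.16	-3.07	-2.60	-3.24	-2.22	-0.83
d	-1.09	0.65	0.86	5.00	0.23	0.47	-1.99	-1.04	-0.75	-0.65	-1.51	-2.78	-4.51	-5.00	-3.96	-2.90
e	-2.61	-1.31	-1.13	0.23	5.00	-0.95	-0.15	-2.03	-2.39	-1.98	-2.12	-3.34	-4.85	-3.46	-4.85	-3.86
f	-2.09	-1.33	-0.56	0.47	-0.95	5.00	-2.82	0.92	-2.34	-0.23	0.41	-1.31	-2.77	-3.78	-3.13	-3.35
g	-1.40	-1.90	-0.40	-1.99	-0.15	-2.82	5.00	-3.40	-3.27	-3.85	-3.15	-2.52	-2.06	0.04	-2.10	-1.55
h	-3.18	-1.76	-1.94	-1.04	-2.03	0.92	-3.40	5.00	-2.73	-1.26	-0.59	-2.13	-3.40	-4.50	-1.83	-3.79
i	-2.54	0.31	-1.88	-0.75	-2.39	-2.34	-3.27	-2.73	5.00	-0.51	-0.92	-2.11	-3.71	-4.29	-4.18	-0.25
j	-2.85	-1.74	-1.67	-0.65	-1.98	-0.23	-3.85	-1.26	-0.51	5.00	-0.13	-1.83	-2.85	-3.83	-4.37	-2.26
k	-3.31	0.11	-2.16	-1.51	-2.12	0.41	-3.15	-0.59	-0.92	-0.13	5.00	0.32	-1.30	-2.41	-2.54	-2.53
l	-2.26	-1.31	-3.07	-2.78	-3.34	-1.31	-2.52	-2.13	-2.11	-1.83	0.32	5.00	0.29	-1.05	-1.33	-2.08
m	-2.69	-2.59	-2.60	-4.51	-4.85	-2.77	-2.06	-3.40	-3.71	-2.85	-1.30	0.29	5.00	0.98	0.58	-0.95
n	-3.37	-3.36	-3.24	-5.00	-3.46	-3.78	0.04	-4.50	-4.29	-3.83	-2.41	-1.05	0.98	5.00	-1.40	-1.82
o	-2.59	-2.55	-2.22	-3.96	-4.85	-3.13	-2.10	-1.83	-4.18	-4.37	-2.54	-1.33	0.58	-1.40	5.00	-1.61
p	-1.85	-1.32	-0.83	-2.90	-3.86	-3.35	-1.55	-3.79	-0.25	-2.26	-2.53	-2.08	-0.95	-1.82	-1.61	5.00
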