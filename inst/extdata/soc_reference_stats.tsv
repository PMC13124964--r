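event_label	a	ror	ror_low	ror_high	prr	chi2	ic	ic025	ebgm	ebgm05
Product issues	41	10.00	7.23	13.83	9.03	296.32	3.17	2.85	9.03	6.54
Investigations	96	6.07	4.82	7.65	4.79	303.95	2.26	2.03	4.79	3.83
Renal and urinary disorders	31	5.01	3.47	7.24	4.69	91.43	2.23	1.85	4.68	3.25
Gastrointestinal disorders	60	3.34	2.54	4.40	2.97	82.97	1.57	1.29	2.97	2.26
Surgical and medical procedures	9	3.21	1.66	6.22	3.16	13.39	1.66	0.99	3.16	1.63
Injury, poisoning and procedural complications	83	2.00	1.57	2.55	1.78	32.32	0.83	0.59	1.78	1.40
Metabolism and nutrition disorders	12	1.89	1.07	3.37	1.87	4.91	0.90	0.31	1.87	1.05
General disorders and administration site conditions	146	1.86	1.51	2.28	1.53	35.68	0.61	0.42	1.53	1.26
Cardiac disorders	12	1.79	1.01	3.17	1.76	4.02	0.82	0.23	1.76	0.99
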