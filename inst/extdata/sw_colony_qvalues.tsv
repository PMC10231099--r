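colony	array_M	array_C	ind_M	ind_C	pool_M	pool_C
c2	0.80	0.20	0.78	0.22	0.60	0.40
c5	0.79	0.21	0.86	0.14	0.65	0.35
c6	0.82	0.18	0.83	0.17	0.74	0.26
c7	0.87	0.13	0.89	0.11	0.80	0.20
c8	0.79	0.21	0.79	0.21	0.73	0.27
c26	0.67	0.33	0.81	0.19	0.70	0.30
c11	0.83	0.17	0.77	0.23	0.62	0.38
c13	0.74	0.26	0.73	0.27	0.53	0.47
c14	0.79	0.21	0.74	0.26	0.72	0.28
c16	0.47	0.53	0.43	0.57	0.51	0.49
c17	0.85	0.15	0.85	0.15	0.73	0.27
c18	0.85	0.15	0.86	0.14	0.76	0.24
c10	0.35	0.65	0.29	0.71	0.41	0.59
c23	0.86	0.14	0.86	0.14	0.78	0.22
c21	0.37	0.63	0.37	0.63	0.36	0.64
c22	0.21	0.79	0.18	0.82	0.18	0.82
c25	0.84	0.16	0.88	0.12	0.80	0.20
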