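colony	f_ligustica	f_carnica	q_pool	q_individual	q_array
c1	0.149	0.146	0.277	no sample	0.189
c2	0.177	0.172	0.398	0.217	0.204
c3	0.122	0.122	0.258	no sample	0.137
c4	0.089	nsi	0.272	no sample	0.226
c5	0.080	nsi	0.348	0.140	0.205
c6	nsi	nsi	0.257	0.173	0.175
c7	0.144	0.141	0.197	0.114	0.127
c8	0.100	0.087	0.274	0.206	0.213
c9	0.084	nsi	0.239	no sample	0.216
c10	0.447	0.467	0.583	0.706	0.652
c11	0.271	0.264	0.380	0.229	0.171
c13	0.247	0.248	0.470	0.274	0.263
c14	0.138	0.132	0.283	0.263	0.208
c15	0.327	0.340	0.471	no sample	0.188
c16	0.263	0.267	0.492	0.569	0.535
c17	0.133	0.126	0.268	0.153	0.150
c18	nsi	nsi	0.239	0.144	0.154
c19	0.452	0.472	0.572	no sample	0.374
c20	0.345	0.351	0.525	no sample	0.434
c21	0.478	0.504	0.644	0.632	0.627
c22	0.629	0.669	0.821	0.816	0.790
c23	0.086	nsi	0.225	0.140	0.144
c24	0.110	0.100	0.305	no sample	0.259
c25	nsi	nsi	0.195	0.123	0.155
c26	0.085	nsi	0.299	0.368	0.327
c28	no sample	no sample	no sample	0.163	no sample
c29	nsi	nsi	0.257	0.168	no sample
c30	0.144	0.147	0.299	0.126	no sample
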