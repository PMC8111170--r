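gene	id	pos	allele_minor	allele_major	maf_adhd	maf_asd	maf_adhd_asd	maf_control	maf_pseudo
SHANK2	rs2000605	70353848	T	C	0.463	0.455	0.472	0.439	0.422
SHANK2	rs11826745	70376203	C	T	0.405	0.444	0.419	0.416	0.413
SHANK2	rs11236570	70379131	A	G	0.416	0.405	0.392	0.421	0.390
SHANK2	rs7113016	70385037	A	G	0.391	0.371	0.407	0.446	0.430
SHANK2	rs4550246	70390048	A	C	0.365	0.362	0.362	0.412	0.396
SHANK2	rs1073294	70401985	G	A	0.448	0.428	0.441	0.400	0.367
SHANK2	rs11236616	70403442	A	G	0.309	0.308	0.367	0.373	0.390
SHANK2	rs7106631	70405829	T	G	0.385	0.407	0.387	0.457	0.484
SHANK2	rs10899158	70405952	T	C	0.460	0.459	0.516	0.438	0.416
SHANK2	rs9888288	70419246	T	A	0.384	0.407	0.458	0.452	0.484
SHANK2	rs12363289	70445161	T	C	0.345	0.338	0.257	0.334	0.312
SHANK2	rs948191	70452995	G	A	0.325	0.362	0.372	0.336	0.348
SHANK2	rs563532	70492408	G	C	0.398	0.432	0.471	0.420	0.437
SHANK3	rs1001469	51138753	A	G	0.411	0.451	0.421	0.405	0.380
SHANK3	rs2341011	51139635	T	C	0.325	0.320	0.351	0.344	0.362
SHANK3	rs739365	51140316	C	T	0.305	0.267	0.248	0.316	0.287
SHANK3	rs2040487	51147015	A	G	0.404	0.410	0.393	0.386	0.390
SHANK3	rs5770820	51150473	G	A	0.502	0.485	0.429	0.487	0.494
SHANK3	rs6010065	51158017	G	C	0.411	0.399	0.392	0.450	0.415
SHANK3	rs8137951	51165664	A	G	0.424	0.428	0.481	0.407	0.449
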