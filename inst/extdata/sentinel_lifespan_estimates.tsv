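variant	locus	chr	bp	allele	table	population	parent	window	lives	deaths	beta	hr	se	p	years	combined
rs429358	APOE	19	45411941	C	1	genetically_british	father	40+	73100	55568	0.0805	1.084	0.0165	1.08e-6	-0.79	FALSE
rs429358	APOE	19	45411941	C	1	genetically_british	mother	40+	75576	45254	0.1426	1.153	0.0182	4.22e-15	-1.24	FALSE
rs429358	APOE	19	45411941	C	1	discovery	both	40+	148676	100822	0.1086	1.115	0.0122	6.29e-19	NA	TRUE
rs429358	APOE	19	45411941	C	1	declared_british	both	40+	20874	13979	0.0341	1.035	0.0337	0.31	NA	FALSE
rs429358	APOE	19	45411941	C	1	other_origins	both	40+	11771	7483	0.1146	1.121	0.0488	0.0189	NA	FALSE
rs429358	APOE	19	45411941	C	1	estonian	offspring	40+	5196	1499	0.1190	1.120	0.0560	0.034	NA	FALSE
rs429358	APOE	19	45411941	C	1	replication	both	40+	37841	22961	0.0716	1.074	0.0248	0.0020	NA	TRUE
rs429358	APOE	19	45411941	C	1	overall	both	40+	186517	123783	0.1014	1.107	0.0110	1.15e-20	NA	TRUE
rs429358	APOE	19	45411941	C	1	discovery	sex_difference	40+	NA	NA	NA	NA	NA	0.011	NA	TRUE
rs10519203	CHRNA3/5	15	78814046	G	1	genetically_british	father	40+	111025	85182	0.0675	1.070	0.0103	4.83e-11	-0.86	FALSE
rs10519203	CHRNA3/5	15	78814046	G	1	genetically_british	mother	40+	115003	69796	0.0403	1.041	0.0113	3.84e-4	-0.60	FALSE
rs10519203	CHRNA3/5	15	78814046	G	1	discovery	both	40+	226028	154978	0.0552	1.057	0.0076	1.95e-13	NA	TRUE
rs10519203	CHRNA3/5	15	78814046	G	1	declared_british	both	40+	31349	21309	0.0675	1.070	0.0206	0.0010	NA	FALSE
rs10519203	CHRNA3/5	15	78814046	G	1	other_origins	both	40+	14223	9308	0.0516	1.053	0.0335	0.124	NA	FALSE
rs10519203	CHRNA3/5	15	78814046	G	1	estonian	offspring	40+	5196	1499	0.1010	1.130	0.0390	0.0100	NA	FALSE
rs10519203	CHRNA3/5	15	78814046	G	1	replication	both	40+	50768	32116	0.0695	1.072	0.0160	6.82e-6	NA	TRUE
rs10519203	CHRNA3/5	15	78814046	G	1	overall	both	40+	276796	187094	0.0579	1.060	0.0069	1.82e-17	NA	TRUE
rs10519203	CHRNA3/5	15	78814046	G	1	discovery	sex_difference	40+	NA	NA	NA	NA	NA	0.075	NA	TRUE
rs429358	APOE	19	45411941	C	2	genetically_british	father	40-75	73100	33393	0.0752	1.0588	0.0212	7.03e-3	-0.30	FALSE
rs429358	APOE	19	45411941	C	2	genetically_british	father	75+	35778	24086	0.1147	1.1216	0.0252	5.34e-6	-0.65	FALSE
rs429358	APOE	19	45411941	C	2	genetically_british	mother	40-75	75576	20780	0.0858	1.0896	0.0268	0.0013	-0.19	FALSE
rs429358	APOE	19	45411941	C	2	genetically_british	mother	75+	46365	25846	0.1847	1.2028	0.0241	1.72e-14	-1.13	FALSE
rs10519203	CHRNA3/5	15	78814046	G	2	genetically_british	father	40-75	111025	51984	0.0924	1.0968	0.0131	1.66e-12	-0.47	FALSE
rs10519203	CHRNA3/5	15	78814046	G	2	genetically_british	father	75+	53244	36139	0.0321	1.0327	0.0158	0.043	-0.16	FALSE
rs10519203	CHRNA3/5	15	78814046	G	2	genetically_british	mother	40-75	115003	32758	0.0565	1.0581	0.0165	6.24e-4	-0.26	FALSE
rs10519203	CHRNA3/5	15	78814046	G	2	genetically_british	mother	75+	69620	39201	0.0292	1.0296	0.0152	0.055	-0.23	FALSE
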