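# Registry of Golden-Gate-compatible endogenous C. elegans donor introns.
# Registered lengths and PATC densities as published for the donor plasmid
# collection; sequences are not shipped (fetch by Addgene accession).
name	plasmid	site	length_bp	patc_density	addgene
smu-1	pCFJ1358	1	296	156	159804
smu-2 intron 3	pCFJ1149	1	1176	605	161516
~250 bp	pCFJ2369	1	274	516	159877
~900 bp	pCFJ2214	1	900	1250	159880
Control (~250 bp)	pCFJ2365	1	276	10	159883
smu-1	pCFJ1359	2	313	98	159805
~250 bp	pCFJ2359	2	275	499	159878
~900 bp	pCFJ2259	2	967	896	159881
Control (~250 bp)	pCFJ2345	2	277	15	159884
smu-1	pCFJ1360	3	966	98	159806
~250 bp	pCFJ2370	3	278	365	159879
~900 bp	pCFJ2215	3	935	1210	159882
Control (~250 bp)	pCFJ2366	3	265	17	159885
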