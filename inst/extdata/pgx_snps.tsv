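rsid	chrom	pos	ref	alt	drug	evidence_level
rs3918290	chr1	97915614	C	T	fluorouracil	1A
rs55886062	chr1	97981343	A	C	fluorouracil	1A
rs67376798	chr1	97547947	T	A	fluorouracil	1A
rs75017182	chr1	97573863	G	C	fluorouracil	1B
rs4148323	chr2	234669144	G	A	irinotecan	2A
rs1800462	chr6	18143955	C	G	mercaptopurine	1A
rs1800460	chr6	18139228	C	T	mercaptopurine	1A
rs1142345	chr6	18130918	T	C	mercaptopurine	1A
rs116855232	chr13	48611934	C	T	mercaptopurine	1A
rs1695	chr11	67352689	A	G	oxaliplatin	2A
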