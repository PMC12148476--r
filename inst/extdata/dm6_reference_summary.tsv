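island_type	seq_id	chrom_length	count	total_bp	median_length
CpG	X	23542271	3066	3407151	NA
CpG	2L	23513712	2269	2105771	NA
CpG	2R	25286936	3179	2906926	NA
CpG	3L	28110227	2784	2589377	NA
CpG	3R	32079331	3701	3542220	NA
CpG	4	1348131	19	17907	NA
CpG	Y	3667352	162	206793	NA
CpG	MT	19524	0	0	NA
CpA	X	23542271	7316	7028647	698
CpA	2L	23513712	7190	6520015	678
CpA	2R	25286936	7358	7384236	687
CpA	3L	28110227	8391	8115587	700
CpA	3R	32079331	9457	9315582	694
CpA	4	1348131	308	265069	629
CpA	Y	3667352	681	1302828	844
CpA	MT	19524	3	1962	557
CpT	X	23542271	7751	7121642	699
CpT	2L	23513712	7420	6516279	676
CpT	2R	25286936	7270	6904591	698
CpT	3L	28110227	8637	8265926	702
CpT	3R	32079331	9814	9023611	689
CpT	4	1348131	365	313929	666
CpT	Y	3667352	781	995309	807
CpT	MT	19524	7	5765	517
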