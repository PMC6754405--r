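protein	start	end	backbone	mods	isomer_group
H3	3	8	TKQTAR	unmod	NA
H3	3	8	TKQTAR	K4me3	NA
H3	3	8	TKQTAR	K4ac	NA
H3	9	17	KSTGGKAPR	unmod	NA
H3	9	17	KSTGGKAPR	K9me1	NA
H3	9	17	KSTGGKAPR	K9me2	NA
H3	9	17	KSTGGKAPR	K9me3	NA
H3	9	17	KSTGGKAPR	K9ac	H3_9_17_ac
H3	9	17	KSTGGKAPR	K14ac	H3_9_17_ac
H3	18	26	KQLATKAAR	unmod	NA
H3	18	26	KQLATKAAR	K18ac	H3_18_26_ac
H3	18	26	KQLATKAAR	K23ac	H3_18_26_ac
H3	18	26	KQLATKAAR	K18acK23ac	NA
H3	27	40	KSAPATGGVKKPHR	unmod	NA
H3	27	40	KSAPATGGVKKPHR	K27me1	NA
H3	27	40	KSAPATGGVKKPHR	K27me3	NA
H3	27	40	KSAPATGGVKKPHR	K36me2	NA
H3	27	40	KSAPATGGVKKPHR	K27me3K36me2	NA
H3	27	40	KSAPATGGVKKPHR	K27ac	NA
H4	4	17	GKGGKGLGKGGAKR	unmod	NA
H4	4	17	GKGGKGLGKGGAKR	K5ac	H4_4_17_ac
H4	4	17	GKGGKGLGKGGAKR	K16ac	H4_4_17_ac
H4	4	17	GKGGKGLGKGGAKR	K5acK8acK12acK16ac	NA
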