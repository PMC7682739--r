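gene	start	end	strand	numbering
tRNA-Phe	577	647	heavy	offset
tRNA-Val	1602	1670	heavy	offset
tRNA-Leu(UUR)	3230	3304	heavy	offset
tRNA-Ile	4263	4331	heavy	offset
tRNA-Gln	4329	4400	light	offset
tRNA-Met	4402	4469	heavy	curated
tRNA-Trp	5512	5579	heavy	curated
tRNA-Ala	5587	5655	light	offset
tRNA-Asn	5657	5729	light	offset
tRNA-Cys	5761	5826	light	curated
tRNA-Tyr	5826	5891	light	offset
tRNA-Ser(UCN)	7446	7514	light	offset
tRNA-Asp	7518	7585	heavy	offset
tRNA-Lys	8295	8364	heavy	offset
tRNA-Gly	9991	10058	heavy	offset
tRNA-Arg	10405	10469	heavy	curated
tRNA-His	12138	12206	heavy	offset
tRNA-Ser(AGY)	12207	12265	heavy	offset
tRNA-Leu(CUN)	12266	12336	heavy	curated
tRNA-Glu	14674	14742	light	offset
tRNA-Thr	15888	15953	heavy	curated
tRNA-Pro	15956	16023	light	offset
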