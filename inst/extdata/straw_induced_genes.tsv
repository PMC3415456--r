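gene_id	cbs_id	gene_set	family	product	rpkm_glucose_48h	rpkm_straw_24h	rpkm_straw_glucose_5h
TID_53159	An07g09330	cazy	GH7	cellobiohydrolase cbhA	6.2	4137.0	21.5
TID_211595	An12g04610	cazy	GH61	endoglucanase-IV-like	3.3	3389.9	54.3
TID_52071	An01g00780	cazy	GH11	endoxylanase xynB	4.4	3015.4	14.9
TID_55136	An03g00960	cazy	GH62	arabinofuranohydrolase axhA	4.1	2521.9	9.3
TID_211544	An12g05010	cazy	CE1	acetyl xylan esterase axeA	1.6	1514.1	5.6
TID_179265	An11g00200	cazy	GH3	beta-glucosidase bglM	1.1	924.6	16.7
TID_43785	An12g02550	cazy	CE1	feruloyl esterase faeC	1.0	902.9	2.5
TID_56619	An14g05800	cazy	GH67	alpha-glucuronidase aguA	1.4	828.3	6.7
TID_57436	An03g00940	cazy	GH10	endoxylanase xynA	0.9	713.0	4.6
TID_54490	An12g02220	cazy	GH6	cellobiosidase cbhC	0.7	611.5	5.7
TID_211053	An14g02760	cazy	GH12	endoglucanase eglA	1.1	510.8	10.8
TID_133986	An08g01760	cazy	GH6	cellobiohydrolase-like	0.4	346.5	4.9
TID_52011	An01g03340	cazy	GH12	xyloglucanase xgeA	1.3	334.4	4.0
TID_183088	An15g04550	cazy	GH11	endoxylanase	0.6	327.4	5.0
TID_209376	An07g08950	cazy	GH5	endoglucanase eglC	0.3	316.2	2.1
TID_125000	An01g04560	cazy	GH16	mixed-linked-glucanase-like	2.0	302.0	58.6
TID_56782	An18g03570	cazy	GH3	beta-glucosidase bglA	2.6	275.8	31.5
TID_47677	An08g01900	cazy	GH43	beta-xylosidase-like	0.4	209.7	1.9
TID_205580	An01g11670	cazy	GH5	endoglucanase-like	0.2	208.2	8.4
TID_45801	An03g00500	cazy	GH30	diglycosidase-like	5.1	147.8	24.5
TID_51773	An01g11660	cazy	GH7	cellobiohydrolase cbhB	0.3	121.1	102.7
TID_135787	An07g08940	cazy	CE16	acetyl-esterase-like	0.1	118.7	0.5
TID_55419	An01g04880	cazy	GH31	alpha-glucosidase axlB	1.8	109.7	0.7
TID_202490	An18g04100	cazy	GH5	glucan-1,3-beta-glucosidase exgA	0.4	99.0	15.2
TID_210947	An14g01130	cazy	PL4	rhamnogalacturonate lyase rglA	0.2	86.2	1.7
TID_43342	An09g03300	cazy	GH31	alpha-xylosidase axlA	3.7	78.8	14.1
TID_203143	An09g01190	cazy	GH43	endoarabinanase abnA	0.1	74.0	2.2
TID_197735	An02g10550	cazy	GH43	endoarabinanase abnC	0.4	61.7	11.1
TID_50997	An17g00300	cazy	GH3	xylosidase-arabinosidase-like	0.4	58.3	1.2
An02g02540	An02g02540	cazy	CE16	acetyl-esterase-like	0.9	56.4	0.5
TID_173684	An02g09690	non_cazy	NA	lipase-I-precursor-like	1.0	1728.9	6.6
TID_51662	An09g00120	non_cazy	NA	ferulic acid esterase faeA	0.9	1100.5	3.7
TID_50877	An13g01880	non_cazy	NA	esterase estA	2.9	317.6	3.0
TID_210730	An16g01880	non_cazy	NA	lysophospholipase-like	0.6	203.7	2.5
TID_54865	NA	non_cazy	NA	GDSL-lipase-like	0.3	168.0	0.7
An03g06560	An03g06560	non_cazy	NA	triacylglycerol-lipase-like	0.2	84.4	0.8
TID_53620	An16g03700	non_cazy	NA	phospholipase-B-like	1.7	62.5	62.5
TID_128530	An07g03340	non_cazy	NA	hydrophobin hyp1	3.5	380.4	423.2
An08g09880	An08g09880	non_cazy	NA	hydrophobin hfbD	0.0	138.5	29.3
TID_188224	An09g00840	non_cazy	NA	hsbA-like surface protein	0.3	118.6	1.0
TID_54125	An18g02730	non_cazy	NA	pth11-like receptor	1.9	70.5	4.1
TID_51997	An01g03740	non_cazy	NA	xylose reductase xyrA	1.1	448.7	2.4
TID_52460	An02g13750	non_cazy	NA	glutaminase-A-like	2.2	213.7	14.7
TID_40496	An15g02410	non_cazy	NA	nitrogen-repression-regulator-like	0.3	132.6	45.3
TID_40740	An15g05990	non_cazy	NA	arabinitol-dehydrogenase-like	0.6	69.6	22.6
TID_56084	An11g10890	non_cazy	NA	UDP-glucose-epimerase-like	2.1	51.2	0.9
TID_56643	An12g09270	non_cazy	NA	lactose permease lac12	3.3	273.4	34.1
TID_38375	An08g04040	non_cazy	NA	quinate-transporter-like	1.7	141.9	2.9
TID_55668	An06g00560	non_cazy	NA	hexose-transporter-like	0.6	124.0	3.7
TID_180069	An07g02540	non_cazy	NA	carboxylic-acid-transporter-like	1.5	108.6	2.0
TID_197549	An02g08230	non_cazy	NA	glucose-transporter-like	1.0	105.4	0.8
TID_54095	An18g01700	non_cazy	NA	quinate-transporter-like	0.2	98.6	1.8
TID_54838	An13g03110	non_cazy	NA	nicotinic-acid-permease-like	0.6	66.6	0.7
TID_120161	An18g05500	non_cazy	NA	ceramidase-like	1.6	144.9	1.1
TID_42809	An18g03380	non_cazy	NA	thioredoxin-like	2.1	98.0	2.8
TID_180489	An07g00070	non_cazy	NA	hypothetical protein	1.1	66.1	25.5
TID_53013	An11g07040	non_cazy	NA	EST-matching hypothetical	0.3	65.5	1.1
TID_43786	An12g02560	non_cazy	NA	tyrosine-phosphatase-like	1.8	51.3	36.1
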