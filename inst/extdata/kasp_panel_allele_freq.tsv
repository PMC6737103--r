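# taxon_n: Oni=30,Omo=22,Oau=23,Oho=16
marker	focal_taxon	diagnostic_allele	excluded_taxon	Oni	Omo	Oau	Oho
Oni3057	Oni	A	NA	100	0	0	0
Oni9497	Oni	T	Oho	100	0	0	31
Oni5782	Oni	A	NA	100	0	0	0
Oni2675	Oni	G	NA	97	0	0	0
Oni1276	Oni	A	NA	97	0	0	0
Omo2657	Omo	A	NA	0	100	0	0
Omo10818	Omo	C	Oho	0	100	0	100
Omo3481	Omo	C	Oho	0	100	0	100
Omo3582	Omo	A	Oho	0	100	0	100
Omo4092	Omo	C	Oho	0	100	0	100
Omo7956	Omo	T	Oho	0	100	0	100
Omo2007	Omo	A	Oho	0	100	0	100
Omo10120	Omo	A	NA	0	95	0	0
Omo8084	Omo	G	Oho	0	91	0	56
Oau9418	Oau	C	NA	0	0	100	0
Oau8029	Oau	G	NA	0	0	100	0
Oau966	Oau	T	NA	0	0	100	0
Oau3873	Oau	C	NA	0	0	100	0
Oau3001	Oau	A	NA	3	0	100	0
Oau2890	Oau	T	NA	12	0	100	0
Oau4411	Oau	T	Oni	5	0	100	0
Oho4270	Oho	A	NA	0	0	0	100
Oho10793	Oho	G	NA	0	0	0	100
Oho10199	Oho	A	NA	0	0	0	100
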