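gene	type	start	end	length	meth_paternal_pct	meth_maternal_pct	region
27448.m000067	MEG	22494	22836	342	100	33	Gene body
27448.m000067	MEG	24533	24799	266	82	37	Gene body
29669.m000820	MEG	182894	183424	530	71	0	Gene body
29609.m000609	MEG	272404	273161	757	96	0	Gene body
29736.m002024	MEG	190784	191231	447	74	7	Gene body
29453.m000062	MEG	-1947	-1727	220	77	0	Upstream
28738.m000149	MEG	-3406	-3119	287	94	0	Upstream
28738.m000149	MEG	110785	111156	371	96	0	Downstream
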