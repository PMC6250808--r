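gene	degree_case	degree_control	kcore_case	kcore_control
IFN-γ	0	41	0	27
IL26	0	38	0	26
TLR3	2	51	2	27
PRKCQ	2	37	2	26
IL17A	4	43	3	26
CDK1	10	53	7	27
TLR4	13	55	7	27
CD274	17	56	7	27
CXCL1	11	44	7	27
BRIP1	11	38	7	27
TNFSF10	1	26	1	21
CD209	9	45	7	26
RRM2	13	45	8	27
SOD2	14	55	9	27
FANCI	17	52	9	27
SELE	11	43	9	27
IL19	18	41	9	27
CCNB2	11	32	7	25
CYP7B1	12	57	10	27
CHEK1	11	52	10	27
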