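Family	Prediction	Homozygous	Hemizygous	Null
HOM01	homozygous	23	0	0
HOM02	homozygous	23	0	0
HOM03	homozygous	23	0	0
HOM04	homozygous	23	0	0
HOM05	homozygous	23	0	0
HOM06	homozygous	23	0	0
HOM07	homozygous	23	0	0
HOM08	homozygous	23	0	0
HOM09	homozygous	23	0	0
HOM10	homozygous	23	0	0
HOM11	homozygous	24	0	0
HOM12	homozygous	24	0	0
HOM13	homozygous	24	0	0
HOM14	homozygous	24	0	0
HOM15	homozygous	24	0	0
HOM16	homozygous	24	0	0
HOM17	homozygous	24	0	0
HOM18	homozygous	24	0	0
HOM19	homozygous	24	0	0
HOM20	homozygous	6	12	5
HEM01	hemizygous	5	12	6
HEM02	hemizygous	5	12	6
HEM03	hemizygous	5	12	6
HEM04	hemizygous	5	12	6
HEM05	hemizygous	5	12	6
HEM06	hemizygous	5	12	6
HEM07	hemizygous	5	12	6
HEM08	hemizygous	5	12	6
HEM09	hemizygous	5	12	6
HEM10	hemizygous	5	12	6
HEM11	hemizygous	5	12	6
HEM12	hemizygous	4	13	6
HEM13	hemizygous	6	11	6
HEM14	hemizygous	5	11	7
HEM15	hemizygous	5	11	7
HEM16	hemizygous	5	11	7
HEM17	hemizygous	5	11	7
HEM18	hemizygous	5	11	7
HEM19	hemizygous	5	11	7
HEM20	hemizygous	5	11	7
HEM21	hemizygous	5	11	7
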