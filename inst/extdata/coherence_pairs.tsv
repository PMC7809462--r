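pair_id	a_anode	a_cathode	b_anode	b_cathode	region_class
1	F8	T8	F7	T7	frontal-central sagittal
2	F4	C4	F3	C3	frontal-central sagittal
3	F3	C3	F8	T8	frontal-central sagittal
4	F4	C4	F7	T7	frontal-central sagittal
5	F3	C3	F7	T7	frontal-central sagittal
6	F4	C4	F8	T8	frontal-central sagittal
7	FZ	CZ	F7	T7	frontal-central sagittal
8	FZ	CZ	F3	C3	frontal-central sagittal
9	FZ	CZ	F8	T8	frontal-central sagittal
10	FZ	CZ	F4	C4	frontal-central sagittal
11	T8	P8	T7	P7	central-parietal sagittal
12	C4	P4	C3	P3	central-parietal sagittal
13	C3	P3	T8	P8	central-parietal sagittal
14	C4	P4	T7	P7	central-parietal sagittal
15	C3	P3	T7	P7	central-parietal sagittal
16	C4	P4	T8	P8	central-parietal sagittal
17	T7	P7	CZ	PZ	central-parietal sagittal
18	C3	P3	CZ	PZ	central-parietal sagittal
19	T8	P8	CZ	PZ	central-parietal sagittal
20	C4	P4	CZ	PZ	central-parietal sagittal
21	P4	O2	P3	O1	parietal-occipital sagittal
22	T7	C3	F7	F3	intrahemispheric lateral
23	P7	P3	F7	F3	intrahemispheric lateral
24	P7	P3	T7	C3	intrahemispheric lateral
25	T8	C4	F8	F4	intrahemispheric lateral
26	P8	P4	F8	F4	intrahemispheric lateral
27	P8	P4	T8	C4	intrahemispheric lateral
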