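# Top-50 adverse events of the full-scale JADER report-based dataset
# (N = 1,865,069 records; suspected drugs only), as published for the survey
# this pipeline implements. "count" is the number of reporting times.
rank	pt_term	count
1	Interstitial lung disease	51347
2	Hepatic function abnormal	33663
3	Platelet count decreased	32904
4	Neutrophil count decreased	27409
5	Pyrexia	25662
6	Pneumonia	25457
7	White blood cell count decreased	25134
8	Anemia	22024
9	Neutropenia	21246
10	Liver disorder	20746
11	Anaphylactic shock	20616
12	Renal impairment	20069
13	Febrile neutropenia	19453
14	Rash	17950
15	Diarrhea	17246
16	Drug eruption	15883
17	Acute kidney injury	14622
18	Decreased appetite	14227
19	Anaphylactic reaction	12298
20	Pancytopenia	12078
21	Stevens-Johnson syndrome	12020
22	Thrombocytopenia	12012
23	Rhabdomyolysis	11998
24	Nausea	11839
25	Blood pressure decreased	11615
26	Cerebral infarction	10860
27	Cardiac failure	10824
28	Myelosuppression	10552
29	Sepsis	10549
30	Erythema multiforme	10516
31	Hypoglycemia	10309
32	Vomiting	10190
33	Hemoglobin decreased	9930
34	Altered state of consciousness	9907
35	Seizure	9624
36	Drug-induced liver injury	9546
37	Death	9010
38	Leukopenia	8875
39	Fatigue	8785
40	Toxic epidermal necrolysis	8152
41	Cerebral hemorrhage	8063
42	Loss of consciousness	7890
43	Erythema	7711
44	Dyspnea	7671
45	Neuroleptic malignant syndrome	7597
46	Drug reaction with eosinophilia and systemic symptoms	7589
47	Pneumocystis jirovecii pneumonia	7405
48	Disseminated intravascular coagulation	7301
49	Agranulocytosis	7066
50	Shock	6741
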