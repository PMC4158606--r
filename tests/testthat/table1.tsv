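condition	a	b	ratio	p
Carpal tunnel syndrome	9	2	56.96	2.47E-09
Urinary tract infection site not specified	26	76	4.33	5.95E-09
Pneumonitis due to inhalation of food or vomitus	15	21	9.041	7.94E-09
Anxiety state unspecified	14	22	8.054	7.39E-08
Unspecified essential hypertension	53	305	2.199	9.73E-08
Esophageal reflux	19	56	4.294	8.60E-07
Unspecified pleural effusion	12	21	7.232	1.55E-06
Friedlander's bacillus infection in conditions classified elsewhere and of unspecified site	6	2	37.97	3.55E-06
Thyrotoxicosis without goiter or other cause and without thyrotoxic crisis or storm	6	2	37.97	3.55E-06
Atrial fibrillation	15	41	4.631	6.17E-06
Other specified disorders of pancreatic internal secretion	4	0	-1	2.80E-05
Other specified idiopathic peripheral neuropathy	4	0	-1	2.80E-05
Pure hypercholesterolemia	20	83	3.05	3.49E-05
Hemorrhage complicating a procedure	5	2	31.64	3.73E-05
Long-term (current) use of steroids	5	3	21.09	9.37E-05
Personal history of noncompliance with medical treatment presenting hazards to health	7	13	6.815	3.47E-04
Hematoma complicating a procedure	4	2	25.31	3.73E-04
Adrenal cortical steroids causing adverse effects in therapeutic use	5	5	12.66	3.73E-04
Nontoxic uninodular goiter	3	0	-1	3.87E-04
Chronic lymphocytic thyroiditis	3	0	-1	3.87E-04
Personal history of malignant neoplasm of bladder	3	0	-1	3.87E-04
Personal history of malignant neoplasm of other endocrine glands and related structures	3	0	-1	3.87E-04
Embolism and thrombosis of other specified veins	4	3	16.88	8.20E-04
Depressive disorder not elsewhere classified	14	62	2.858	9.55E-04
Toxic diffuse goiter without thyrotoxic crisis or storm	3	1	37.97	0.001465
Unspecified idiopathic peripheral neuropathy	3	1	37.97	0.001465
Unspecified disorder of optic nerve and visual pathways	3	1	37.97	0.001465
Personal history of tobacco use	8	24	4.219	0.001632
Diabetes mellitus without complication type i not stated as uncontrolled	8	25	4.05	0.002022
Hypertrophy (benign) of prostate without urinary obstruction	5	9	7.032	0.002323
Bipolar disorder, unspecified	4	5	10.13	0.002624
Unspecified disorder of thyroid	3	2	18.99	0.003465
Retention of urine unspecified	3	2	18.99	0.003465
Other specified retention of urine	3	2	18.99	0.003465
Migraine unspecified without mention of intractable migraine without mention of status migrainosus	4	6	8.438	0.004125
Other pulmonary embolism and infarction	4	6	8.438	0.004125
Unspecified sleep apnea	4	6	8.438	0.004125
Anemia unspecified	11	53	2.627	0.005828
Methicillin susceptible staphylococcus aureus	3	3	12.66	0.006558
Obstructive sleep apnea (adult)(pediatric)	3	3	12.66	0.006558
Tracheostomy status	4	10	5.063	0.015584
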