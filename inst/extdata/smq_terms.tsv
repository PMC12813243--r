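smq_code	pt_code	pt_name	scope
20000001	10000101	Gastrointestinal disorder	narrow
20000001	10000102	Gastrointestinal pain	broad
20000002	10000201	Diarrhoea	narrow
20000002	10000202	Diarrhoea haemorrhagic	narrow
20000002	10000203	Frequent bowel movements	broad
20000002	10000204	Defaecation urgency	broad
20000003	10000301	Nausea	narrow
20000003	10000302	Vomiting	narrow
20000003	10000303	Abdominal discomfort	narrow
20000003	10000304	Abdominal distension	broad
20000003	10000305	Dyspepsia	broad
20000004	10000401	Pancytopenia	narrow
20000004	10000402	Neutropenia	narrow
20000004	10000403	Thrombocytopenia	narrow
20000004	10000404	Anaemia	narrow
20000004	10000405	White blood cell count decreased	broad
20000005	10000501	Bicytopenia	narrow
20000005	10000502	Febrile bone marrow aplasia	narrow
20000005	10000503	Full blood count decreased	broad
20000006	10000601	Acute kidney injury	narrow
20000006	10000602	Renal failure	narrow
20000006	10000603	Anuria	narrow
20000006	10000604	Blood creatinine increased	broad
20000006	10000605	Glomerular filtration rate decreased	broad
20000007	10000701	Interstitial lung disease	narrow
20000007	10000702	Pneumonitis	narrow
20000007	10000703	Pulmonary fibrosis	narrow
20000007	10000704	Lung opacity	broad
20000007	10000705	Dyspnoea exertional	broad
20000008	10000801	Atrial fibrillation	narrow
20000008	10000802	Ventricular tachycardia	narrow
20000008	10000803	Electrocardiogram QT prolonged	narrow
20000008	10000804	Palpitations	broad
20000008	10000805	Heart rate irregular	broad
20000009	10000901	Hepatotoxicity	narrow
20000009	10000902	Hepatic failure	narrow
20000009	10000903	Alanine aminotransferase increased	narrow
20000009	10000904	Liver function test increased	broad
20000009	10000905	Hyperbilirubinaemia	broad
20000010	10001001	Dementia	narrow
20000010	10001002	Dementia Alzheimer's type	narrow
20000010	10001003	Cognitive disorder	broad
20000010	10001004	Memory impairment	broad
20000011	10001101	Deafness	narrow
20000011	10001102	Hypoacusis	narrow
20000011	10001103	Vertigo	narrow
20000011	10001104	Tinnitus	broad
20000011	10001105	Balance disorder	broad
20000012	10001201	Pulmonary embolism	narrow
20000012	10001202	Deep vein thrombosis	narrow
20000012	10001203	Cerebrovascular accident	narrow
20000012	10001204	Thrombosis	narrow
20000012	10001205	Embolism venous	broad
20000012	10001206	Blood fibrin D dimer increased	broad
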