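smq_code	smq_name	parent_code	status
20000001	Gastrointestinal disorders (toy SMQ)		A
20000002	Noninfectious diarrhoea (toy SMQ)	20000001	A
20000003	Gastrointestinal nonspecific symptoms (toy SMQ)	20000001	A
20000004	Haematopoietic cytopenias (toy SMQ)		A
20000005	Cytopenias affecting more than one type of blood cell (toy SMQ)	20000004	A
20000006	Acute renal failure (toy SMQ)		A
20000007	Interstitial lung disease (toy SMQ)		A
20000008	Cardiac arrhythmias (toy SMQ)		A
20000009	Hepatic disorders (toy SMQ)		A
20000010	Dementia (toy SMQ)		A
20000011	Hearing and vestibular disorders (toy SMQ)		A
20000012	Embolic and thrombotic events (toy SMQ)		A
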