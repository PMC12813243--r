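canonical	synonym	class
palbociclib	IBRANCE	cdk46i
palbociclib	PALBOCICLIB CAPSULE	cdk46i
ribociclib	KISQALI	cdk46i
ribociclib	RIBOCICLIB SUCCINATE	cdk46i
abemaciclib	VERZENIO	cdk46i
abemaciclib	VERZENIOS	cdk46i
letrozole	FEMARA	endocrine
anastrozole	ARIMIDEX	endocrine
exemestane	AROMASIN	endocrine
tamoxifen	NOLVADEX	endocrine
tamoxifen	TAMOXIFEN CITRATE	endocrine
fulvestrant	FASLODEX	endocrine
goserelin	ZOLADEX	endocrine
capecitabine	XELODA	chemotherapy
paclitaxel	TAXOL	chemotherapy
docetaxel	TAXOTERE	chemotherapy
cyclophosphamide	CYTOXAN	chemotherapy
doxorubicin	ADRIAMYCIN	chemotherapy
carboplatin	PARAPLATIN	chemotherapy
gemcitabine	GEMZAR	chemotherapy
vinorelbine	NAVELBINE	chemotherapy
eribulin	HALAVEN	chemotherapy
trastuzumab	HERCEPTIN	other_targeted
pertuzumab	PERJETA	other_targeted
everolimus	AFINITOR	other_targeted
alpelisib	PIQRAY	other_targeted
lapatinib	TYKERB	other_targeted
olaparib	LYNPARZA	other_targeted
bevacizumab	AVASTIN	other_targeted
pembrolizumab	KEYTRUDA	immune_checkpoint
atezolizumab	TECENTRIQ	immune_checkpoint
nivolumab	OPDIVO	immune_checkpoint
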