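variant	ingredient
# brand names
GEMZAR	GEMCITABINE
BUSULFEX	BUSULFAN
MYLERAN	BUSULFAN
THYMOGLOBULIN	ANTI-THYMOCYTE GLOBULIN
ATGAM	ANTI-THYMOCYTE GLOBULIN
PROGRAF	TACROLIMUS
ADVAGRAF	TACROLIMUS
NUVARING	ETONOGESTREL AND ETHINYLESTRADIOL VAGINAL RING
SOLIRIS	ECULIZUMAB
NEORAL	CICLOSPORIN
SANDIMMUNE	CICLOSPORIN
CYCLOSPORINE	CICLOSPORIN
CELLCEPT	MYCOPHENOLATE MOFETIL
TYLENOL	PARACETAMOL
ACETAMINOPHEN	PARACETAMOL
CYTOXAN	CYCLOPHOSPHAMIDE
AVASTIN	BEVACIZUMAB
PARAPLATIN	CARBOPLATIN
DECADRON	DEXAMETHASONE
SUTENT	SUNITINIB
CYTOSAR-U	CYTARABINE
OPDIVO	NIVOLUMAB
LAMICTAL	LAMOTRIGINE
KEYTRUDA	PEMBROLIZUMAB
ADVIL	IBUPROFEN
MOTRIN	IBUPROFEN
XELODA	CAPECITABINE
GLUCOPHAGE	METFORMIN
CIPRO	CIPROFLOXACIN
RHEUMATREX	METHOTREXATE
RITUXAN	RITUXIMAB
MABTHERA	RITUXIMAB
REMICADE	INFLIXIMAB
COUMADIN	WARFARIN
LOVENOX	ENOXAPARIN
PLAVIX	CLOPIDOGREL
XARELTO	RIVAROXABAN
ELIQUIS	APIXABAN
PRADAXA	DABIGATRAN ETEXILATE
# salt / formulation variants
TACROLIMUS MONOHYDRATE	TACROLIMUS
METFORMIN HYDROCHLORIDE	METFORMIN
METFORMIN HCL	METFORMIN
CIPROFLOXACIN HYDROCHLORIDE	CIPROFLOXACIN
GEMCITABINE HYDROCHLORIDE	GEMCITABINE
SUNITINIB MALATE	SUNITINIB
METHOTREXATE SODIUM	METHOTREXATE
PREDNISOLONE SODIUM PHOSPHATE	PREDNISOLONE
DEXAMETHASONE SODIUM PHOSPHATE	DEXAMETHASONE
ASPIRIN (ACETYLSALICYLIC ACID)	ASPIRIN
ACETYLSALICYLIC ACID	ASPIRIN
HEPARIN SODIUM	HEPARIN
ENOXAPARIN SODIUM	ENOXAPARIN
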