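ingredient	atc_class
GEMCITABINE	antineoplastic agents
BUSULFAN	antineoplastic agents
CYCLOPHOSPHAMIDE	antineoplastic agents
BEVACIZUMAB	antineoplastic agents
CARBOPLATIN	antineoplastic agents
CISPLATIN	antineoplastic agents
OXALIPLATIN	antineoplastic agents
SUNITINIB	antineoplastic agents
CYTARABINE	antineoplastic agents
NIVOLUMAB	antineoplastic agents
PEMBROLIZUMAB	antineoplastic agents
CAPECITABINE	antineoplastic agents
METHOTREXATE	antineoplastic agents
FLUOROURACIL	antineoplastic agents
PACLITAXEL	antineoplastic agents
DOCETAXEL	antineoplastic agents
RITUXIMAB	antineoplastic agents
ANTI-THYMOCYTE GLOBULIN	immunosuppressants
TACROLIMUS	immunosuppressants
ECULIZUMAB	immunosuppressants
CICLOSPORIN	immunosuppressants
MYCOPHENOLATE MOFETIL	immunosuppressants
AZATHIOPRINE	immunosuppressants
SIROLIMUS	immunosuppressants
EVEROLIMUS	immunosuppressants
INFLIXIMAB	immunosuppressants
ADALIMUMAB	immunosuppressants
PARACETAMOL	analgesics
IBUPROFEN	analgesics
NAPROXEN	analgesics
DICLOFENAC	analgesics
TRAMADOL	analgesics
PREDNISOLONE	corticosteroids for systemic use
PREDNISONE	corticosteroids for systemic use
DEXAMETHASONE	corticosteroids for systemic use
METHYLPREDNISOLONE	corticosteroids for systemic use
HYDROCORTISONE	corticosteroids for systemic use
ETONOGESTREL AND ETHINYLESTRADIOL VAGINAL RING	sex hormones and modulators of the genital system
LEVONORGESTREL AND ETHINYLESTRADIOL	sex hormones and modulators of the genital system
DROSPIRENONE AND ETHINYLESTRADIOL	sex hormones and modulators of the genital system
ESTRADIOL	sex hormones and modulators of the genital system
LAMOTRIGINE	antiepileptics
VALPROATE	antiepileptics
LEVETIRACETAM	antiepileptics
CARBAMAZEPINE	antiepileptics
PHENYTOIN	antiepileptics
METFORMIN	drugs used in diabetes
INSULIN GLARGINE	drugs used in diabetes
GLICLAZIDE	drugs used in diabetes
SITAGLIPTIN	drugs used in diabetes
EMPAGLIFLOZIN	drugs used in diabetes
CIPROFLOXACIN	antibacterials for systemic use
LEVOFLOXACIN	antibacterials for systemic use
CEFOPERAZONE AND SULBACTAM	antibacterials for systemic use
TIGECYCLINE	antibacterials for systemic use
LINEZOLID	antibacterials for systemic use
VANCOMYCIN	antibacterials for systemic use
AMOXICILLIN	antibacterials for systemic use
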