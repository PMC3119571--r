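gene,subdomain,tumor,effect,description,aliases,citations,source
EGFR,PL,lung,activating,,,b31;b32,table1
EGFR,aC,lung,activating,,,b31;b32;b33;b49,table1
EGFR,aC-b4,lung,activating,,,b50;b51,table1
EGFR,HC,lung,activating,,,b31;b32;b33;b49,table1
EGFR,AD1,lung,activating,,,b49,table1
EGFR,aC-b4,skin,activating,,,b52,table1
EGFR,aC,breast,activating,,,b53,table1
EGFR,aC,prostate,activating,,,b54,table1
ErbB2,aC,lung,activating,,,b55,table1
ErbB2,aC-b4,lung,activating,,,b56;b57;b58,table1
ErbB2,aC-b4,colon,activating,,,b55,table1
ErbB2,aC-b4,breast,activating,,,b55,table1
ErbB2,aC,breast,activating,,,b59,table1
ErbB4,AL,colon,activating,,,b60,table1
ErbB4,AL,skin,activating,,,b61,table1
ErbB4,AL,breast,activating,,,b60,table1
PDGFRA,JM,lung,activating,,,b62,table1
PDGFRA,CT,lung,activating,,,b63,table1
PDGFRA,AL,leukemia,activating,,,b64,table1
CSF1R,CT,leukemia,activating,,,b65;b66,table1
KIT,JM,lung,activating,,,b67,table1
KIT,JM,skin,activating,,,b68;b69;b70;b71,table1
KIT,aC,skin,activating,,,b69;b71,table1
KIT,AL,skin,activating,,,b69;b70;b71,table1
KIT,JM,leukemia,activating,,,b72;b73,table1
KIT,AL,leukemia,activating,,,b72;b73;b74;b75,table1
FLT3,JM,leukemia,activating,,,b76;b77;b78,table1
FLT3,AL,leukemia,activating,,,b79;b80,table1
VEGFR2,CT,lung,activating,,,b62,table1
VEGFR2,TM,breast,activating,,,b81,table1
VEGFR2,AL,breast,activating,,,b81,table1
FGFR1,AL,lung,activating,,,b63,table1
FGFR2,JM,skin,loss-of-function,,,b82,table1
FGFR2,aC,skin,loss-of-function,,,b82,table1
FGFR2,AL,skin,loss-of-function,,,b82,table1
FGFR3,AL,skin,activating,,,b83;b84;b85,table1
FGFR3,AL,leukemia,activating,,,b86;b87;b88,table1
FGFR4,AL,lung,activating,,,b62,table1
MET,JM,lung,activating,,,b62;b89,table1
MET,aC,colon,activating,,,b90,table1
EPHA,AL,lung,activating,,,b62;b63,table1
EPHA,CT,lung,activating,,,b62,table1
LTK,AL,lung,activating,,,b62,table1
LTK,CT,lung,activating,,,b62,table1
EGFR,aC,kidney,activating,,,b95;b96,table2
EGFR,aC,thyroid,activating,,,b97,table2
EGFR,AL,thyroid,activating,,,b97,table2
EGFR,AD1,thyroid,activating,,,b98,table2
ErbB2,aC-b4,ovary,activating,,,b99;b100;b101,table2
ErbB4,aC,gastrointestinal,activating,,,b60,table2
PDGFRA,AL,gastrointestinal,activating,,,b102;b103;b104,table2
PDGFRA,JM,gastrointestinal,activating,,,b102;b103;b104,table2
KIT,AL,ovary,activating,,,b105;b106,table2
KIT,JM,gastrointestinal,activating,,,b107;b108;b109;b110,table2
MET,JM,thyroid,activating,,,b111;b112,table2
RET,AD2,thyroid,activating,,,b113;b114;b115;b116,table2
RET,JM,thyroid,activating,,,b116;b117,table2
RET,AL,thyroid,activating,,,b118,table2
ALK,AL,neuroblastoma,activating,,,b119;b120;b121;b122,table2
ALK,aC,neuroblastoma,activating,,,b120;b121;b122,table2
EGFR,HC,lung,activating,L834R,,b31;b32;b33,text
EGFR,aC,lung,activating,del 723-729 ins S,del L723-P729 ins S|del 728-729insS,b30;b31,text
EGFR,N-lobe,lung,resistance,T766M,,b127;b128,text
EGFR,HC,lung,resistance,L834R/T766M,,b128;b157;b158,text
EGFR,N-lobe,lung,activating,E685S,E685G,b30;b31;b49,text
EGFR,PL,lung,activating,G695S,,b30;b31;b49,text
EGFR,aC-b4,lung,activating,S744I,,b30;b31;b49,text
EGFR,AL,lung,activating,L837Q,,b30;b31;b49,text
ErbB2,aC-b4,lung,activating,G776^YVMA^,,b56;b57;b58,text
ErbB4,AL,skin,activating,E836K,,b61,text
ErbB4,AL,skin,activating,E872K,,b61,text
ErbB4,C-lobe,skin,activating,G936R,,b61,text
ErbB4,PL,lung,loss-of-function,G802dup,,b94,text
ErbB4,AL,lung,loss-of-function,D861Y,,b94,text
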