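kinase,subdomain,start,end,basis
EGFR,JM,645,671,upstream of the kinase domain N-lobe
EGFR,N-lobe,672,767,kinase domain start to the hinge (gatekeeper T766)
EGFR,C-lobe,768,960,hinge to kinase domain end
EGFR,PL,695,700,glycine-rich GxGxxG nucleotide-binding loop
EGFR,aC,729,740,regulatory helix carrying E734/E738
EGFR,aC-b4,741,752,loop between the aC-helix and the b4 strand
EGFR,C-loop,806,818,catalytic loop around the HRD aspartate D813
EGFR,AL,831,852,DFG start D831 plus ~20 residues (contains Y845)
EGFR,CT,961,1210,C-terminal tail (docking tyrosines)
ErbB2,JM,677,703,EGFR span shifted by the +32 family alignment
ErbB2,N-lobe,704,799,EGFR span +32
ErbB2,C-lobe,800,992,EGFR span +32
ErbB2,PL,727,732,EGFR span +32
ErbB2,aC,761,772,EGFR span +32 (E766/E770)
ErbB2,aC-b4,773,784,eight-residue loop carrying the hydrophobic patch
ErbB2,C-loop,838,850,EGFR span +32 (D845)
ErbB2,AL,863,884,DFG start D863 plus ~20 residues (contains Y877)
ErbB2,CT,993,1255,EGFR span +32
ErbB3,JM,647,673,EGFR span shifted by the +2 family alignment
ErbB3,N-lobe,674,769,EGFR span +2
ErbB3,C-lobe,770,962,EGFR span +2
ErbB3,PL,697,702,EGFR span +2
ErbB3,aC,731,742,EGFR span +2
ErbB3,aC-b4,743,754,EGFR span +2
ErbB3,C-loop,808,820,EGFR span +2 (N815)
ErbB3,AL,833,854,DFG-homologous start D833 plus ~20 residues
ErbB3,CT,963,1210,EGFR span +2
ErbB4,JM,650,676,EGFR span shifted by the +5 family alignment
ErbB4,N-lobe,677,772,EGFR span +5
ErbB4,C-lobe,773,965,EGFR span +5
ErbB4,PL,700,705,EGFR span +5
ErbB4,aC,734,745,EGFR span +5 (E739/E743)
ErbB4,aC-b4,746,757,EGFR span +5
ErbB4,C-loop,811,823,EGFR span +5 (D818)
ErbB4,AL,836,857,DFG start D836 plus ~20 residues (contains Y850)
ErbB4,CT,966,1215,EGFR span +5
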