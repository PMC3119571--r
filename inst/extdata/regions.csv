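kinase,region,residues,anchor,provisional
EGFR,R-spine,742;753;811;832,872,FALSE
EGFR,C-spine,702;719;774;819;820;821;879;883,,FALSE
EGFR,hydrophobic-core,736;742;834;837;838,,TRUE
EGFR,dimer-interface-N,680;682;736;758;762,,FALSE
EGFR,dimer-interface-C,917;920;921;924;928,,FALSE
EGFR,aC-b4,741;742;744;745;746;750;829;830;832;834;837,,TRUE
ErbB2,R-spine,774;785;843;864,904,TRUE
ErbB2,C-spine,734;751;806;851;852;853;911;915,,TRUE
ErbB2,aC-b4,773;774;776;777;778;782;861;862;864;866;869,,FALSE
ErbB3,R-spine,744;755;813;834,874,TRUE
ErbB3,C-spine,704;721;776;821;822;823;881;885,,TRUE
ErbB4,R-spine,747;758;816;837,877,TRUE
ErbB4,C-spine,707;724;779;824;825;826;884;888,,TRUE
ErbB4,hydrophobic-core,741;747;839;842;843,,TRUE
ErbB4,aC-b4,746;747;749;750;751;755;834;835;837;839;842,,TRUE
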