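drug,resistant,sensitive,source
17-AAG,5.000,5.002,literature
AEW541,5.299,5.615,statistical
AZD0530,5.910,6.262,literature
AZD6244,5.618,5.970,literature
Erlotinib,5.562,5.915,literature
Irinotecan,5.592,5.944,literature
L-685458,5.290,5.626,statistical
LBW242,5.605,6.003,statistical
Lapatinib,5.579,5.931,literature
Nilotinib,5.593,5.945,literature
Nutlin-3,5.336,5.512,statistical
PD-0325901,6.269,6.621,literature
PD-0332991,6.186,6.539,literature
PF2341066,6.045,6.397,literature
PHA-665752,5.303,5.616,statistical
PLX4720,5.392,5.682,statistical
Paclitaxel,5.000,5.267,literature
Panobinostat,6.541,6.894,literature
RAF265,5.718,6.125,statistical
Sorafenib,5.000,5.110,literature
TAE684,5.477,5.755,statistical
TKI258,5.925,6.277,literature
Topotecan,7.563,7.916,literature
ZD-6474,6.219,6.571,statistical
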