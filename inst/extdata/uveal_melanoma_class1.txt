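# Class 1 uveal melanoma biomarker genes (low metastatic risk)
EIF1B
FXR1
ID2
LMCD1
LTA4H
MTUS1
ROBO1
SATB1
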