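# Class 2 uveal melanoma biomarker genes (high metastatic risk)
CDH1
ECM1
HTR2B
RRAB31
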