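VENOUS	THROMBOSIS
STROKE	THROMBOSIS
AMI	THROMBOSIS
PULMONARY	THROMBOSIS
ARTERIAL	THROMBOSIS
OTHER_THROMB	THROMBOSIS
SPONT_AB	THROMBOSIS
ANTICOAG	THROMBOSIS
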