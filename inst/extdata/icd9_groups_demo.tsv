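451.1	VENOUS
451.2	VENOUS
453.0	VENOUS
453.8	VENOUS
434.91	STROKE
434.01	STROKE
436	STROKE
410.01	AMI
410.11	AMI
410.91	AMI
415.11	PULMONARY
415.19	PULMONARY
444.0	ARTERIAL
444.21	ARTERIAL
444.22	ARTERIAL
286.6	OTHER_THROMB
289.81	OTHER_THROMB
453.1	OTHER_THROMB
634.90	SPONT_AB
634.91	SPONT_AB
V58.61	ANTICOAG
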