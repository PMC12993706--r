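model,month,kernel,units
CAM5_synthetic,1,78,per_unit
CAM5_synthetic,2,95,per_unit
CAM5_synthetic,3,122,per_unit
CAM5_synthetic,4,148,per_unit
CAM5_synthetic,5,168,per_unit
CAM5_synthetic,6,182,per_unit
CAM5_synthetic,7,180,per_unit
CAM5_synthetic,8,162,per_unit
CAM5_synthetic,9,134,per_unit
CAM5_synthetic,10,104,per_unit
CAM5_synthetic,11,82,per_unit
CAM5_synthetic,12,72,per_unit
HadGEM2_synthetic,1,0.74,per_0.01
HadGEM2_synthetic,2,0.90,per_0.01
HadGEM2_synthetic,3,1.16,per_0.01
HadGEM2_synthetic,4,1.41,per_0.01
HadGEM2_synthetic,5,1.61,per_0.01
HadGEM2_synthetic,6,1.75,per_0.01
HadGEM2_synthetic,7,1.73,per_0.01
HadGEM2_synthetic,8,1.55,per_0.01
HadGEM2_synthetic,9,1.27,per_0.01
HadGEM2_synthetic,10,0.98,per_0.01
HadGEM2_synthetic,11,0.77,per_0.01
HadGEM2_synthetic,12,0.68,per_0.01
HadGEM3_synthetic,1,81,per_unit
HadGEM3_synthetic,2,99,per_unit
HadGEM3_synthetic,3,127,per_unit
HadGEM3_synthetic,4,153,per_unit
HadGEM3_synthetic,5,173,per_unit
HadGEM3_synthetic,6,188,per_unit
HadGEM3_synthetic,7,186,per_unit
HadGEM3_synthetic,8,168,per_unit
HadGEM3_synthetic,9,139,per_unit
HadGEM3_synthetic,10,108,per_unit
HadGEM3_synthetic,11,85,per_unit
HadGEM3_synthetic,12,75,per_unit
CACK_synthetic,1,76,per_unit
CACK_synthetic,2,93,per_unit
CACK_synthetic,3,119,per_unit
CACK_synthetic,4,144,per_unit
CACK_synthetic,5,164,per_unit
CACK_synthetic,6,178,per_unit
CACK_synthetic,7,176,per_unit
CACK_synthetic,8,158,per_unit
CACK_synthetic,9,131,per_unit
CACK_synthetic,10,101,per_unit
CACK_synthetic,11,80,per_unit
CACK_synthetic,12,70,per_unit
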