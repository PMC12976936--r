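# SYNTHETIC stand-in for postoperative graft-placement measurements (no
# imaging data are deposited): four animals, translations in mm along
# anatomical L-R / A-P / I-S, rotations in degrees (right-hand rule),
# volume ratio = designed / postoperative graft volume.
animal,graft_type,t_LR,t_AP,t_IS,r_LR,r_AP,r_IS,volume_ratio
pig_1,tubular,2.1,-0.4,-1.2,38,3,2,0.72
pig_2,branched,1.5,0.6,-2.0,5,-2,3,1.18
pig_3,branched,6.9,-0.8,-3.1,-8,6,12,0.95
pig_4,branched,3.4,0.3,-2.4,10,-5,6,0.85
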