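# Printed ground-truth (GT) and CNN-predicted (Exp) region measurements for
# the four experimental phantoms: diameters (mm) and tank-centred centre
# coordinates (mm).
phantom,region,gt_dia,exp_dia,gt_cx,gt_cy,exp_cx,exp_cy
A,phantom,30.50,28.99,0.08,0.25,0.55,0.05
A,inclusion_1,10.00,9.87,-5.83,5.92,-5.25,5.44
B,phantom,30.50,28.59,0.08,0.25,0.31,0.00
B,inclusion_1,10.00,9.24,-5.83,5.92,-5.47,5.69
C,phantom,30.02,29.13,-0.65,0.24,-0.43,-0.58
C,inclusion_1,9.36,9.30,-5.57,3.95,-5.73,3.02
C,inclusion_2,5.82,5.81,2.91,-5.00,2.95,-5.75
D,phantom,30.02,28.98,-0.65,0.24,-0.33,-0.49
D,inclusion_1,9.36,8.92,-5.57,3.95,-5.15,2.76
D,inclusion_2,5.82,4.35,2.91,-5.00,3.78,-6.24
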