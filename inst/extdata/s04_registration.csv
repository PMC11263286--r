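channel,ba_label,hemisphere,mni_x,mni_y,mni_z,probability
14,4,L,-6.33,-35.33,79,0.756
15,4,L,-17.67,-35.67,78,0.566
16,4,L,-31,-35,73.67,0.48
24,6,L,-16.67,-16.67,78,0.723
25,6,L,-29.67,-18.33,74,0.681
26,4,L,-43.333,19.333,66.667,0.642
32,6,L,-5.67,-4.67,75.33,1
33,6,L,-15.67,-3.33,75.33,1
34,6,L,-29.33,-3.67,69.33,1
35,6,L,-41.67,-2.67,62.33,0.912
36,6,L,-54,-3.33,52.67,0.825
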