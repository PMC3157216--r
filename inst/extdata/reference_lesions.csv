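diameter_mm,x,y,z,placement_class
4,103,123,52,interior_wm
6,106,84,63,interior_wm
8,110,105,45,interior_wm
10,151,127,58,interior_wm
4,142,144,52,wm_gm_border
6,144,86,63,wm_gm_border
8,139,140,45,wm_gm_border
10,109,141,58,wm_gm_border
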