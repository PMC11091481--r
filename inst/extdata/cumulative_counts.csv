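room,time_point,n_wt_hom,n_het,n_ko_hom
room1,0,338,576,267
room2,0,329,584,292
room3,0,216,264,98
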