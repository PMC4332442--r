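slice_index,x_mm,y_mm
1,-20,-20
1,20,-20
1,20,20
1,-20,20
2,-22,-22
2,22,-22
2,22,22
2,-22,22
3,-20,-20
3,20,-20
3,20,20
3,-20,20
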