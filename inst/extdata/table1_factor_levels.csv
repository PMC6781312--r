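factor,name,units,low,high
A,pre_mixing_time,min,5,15
B,impeller_rate,rpm,400,600
C,binder_amount,%,20,24
D,liquid_additive_rate,mL/min,10,20
E,granulation_time,min,3,5
F,lubrication_time,min,10,20
G,min_punch_tip_separation,mm,3.0,3.2
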