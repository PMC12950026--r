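trial,battery,ramp_velocity,hold_angle,ss,peak
1,velocity,980,37,80,166
2,velocity,604,37,80,152
3,velocity,352,37,80,138
4,velocity,188,37,80,127
5,velocity,96,37,80,118
6,hold_angle,240.4,60,110,165
7,hold_angle,240.4,46,88,132
8,hold_angle,240.4,34,65,98
9,hold_angle,240.4,23,40,60
10,hold_angle,240.4,15,0,45
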