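name,symbol,unit,center,step
agar_concentration,Y1,%,0.6,0.1
light_duration,Y2,h/d,12,2
culture_temperature,Y3,degC,28,4
relative_humidity,Y4,%,70,10
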