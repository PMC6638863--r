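# Forest inventory plot, Willow Creek (Chequamegon-Nicolet NF, Wisconsin).
# Circular plot, radius 20 m; each record is one stem (density = 1/plot area).
pft,dbh_cm
late,23.5
early,5.3
late,28.7
late,8.6
late,7.1
late,26.4
late,22.5
late,8.9
late,30.2
late,30.4
late,8.6
late,20.4
late,7.4
late,29.6
early,6
late,28
late,26.5
late,23.7
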