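scheme,design,n_plots,n_nights,field_hours,seq_per_night_plot
GA+GR+CA full night,GAP+GROUND+CANOPY,2,11,14.8,2069
GA+GR+CA full night,GAP+GROUND+CANOPY,3,6,9.6,2069
GA+GR+CA full night,GAP+GROUND+CANOPY,4,4,6.9,2069
GA+GR full night,GAP+GROUND,2,16,15.2,1524
GA+GR full night,GAP+GROUND,3,9,8.7,1524
GA+GR full night,GAP+GROUND,4,6,7.2,1524
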