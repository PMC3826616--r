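foldThreshold: 25
bandwidth: 100
prelimBandwidth: 50
kurtosisMax: 50
minStrandCorr: 0.3
maxRegionLength: 500
minShift: 25
maxShift: 150
curveBw: 5
topShiftRegions: 1000
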