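>synthetic_lipoprotein | synthetic 170-residue sequence drawn from average globular-protein amino-acid frequencies; stand-in for a mature outer-membrane lipoprotein sequence
KLDITQEEGAETSLYNNARNEQKQYSQFRLLALSLLDLGPSYYRNGLAPNETKEILLEDW
DTVKPKSQRLKKEGKESFNVRDAAAGMALADMSAFHADGYTGRLYYMLKLFLLEARMLVI
KVESLYHLLLFMIKQKDEVKGIADFELMIWNVKGGKQKHVGVIVAVLENL
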