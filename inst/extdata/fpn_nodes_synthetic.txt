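# SYNTHETIC stand-in frontoparietal node set for the generator's R1..R78
# labels (the atlas-matched membership table is not distributed with this
# package; supply your own file for real data). One label per line.
R1
R6
R11
R16
R21
R26
R31
R36
R41
R46
R51
R56
R61
R66
R71
R76
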