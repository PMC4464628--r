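enzyme_label	ko
AACT	K00626
HMGS	K01641
HMGR	K00021
MK	K00869
PMK	K00938
MVD	K01597
DXS	K01662
DXR	K00099
CDP-MEK	K00919
MEP-CT	K00991
MECDPS	K01770
HMBPPS	K03526
HMBPPR	K03527
IDI	K01823
FPS	K00787
GPS	K13789
SS	K00801
SE	K00511
Beta-AS	K15813
DS	K15817
PPDS	K17847
PPTS	K17848
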