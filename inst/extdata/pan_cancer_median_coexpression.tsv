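gene	median_r
CD2	0.955
CD247	0.944
SIRPG	0.942
CD3D	0.933
LCK	0.918
SIT1	0.917
CD6	0.912
CXCR3	0.910
SH2D1A	0.907
SLA2	0.904
SLAMF6	0.902
ITGAL	0.897
TIGIT	0.896
CD96	0.896
TRAF3IP3	0.892
ACAP1	0.882
RASAL3	0.882
ITK	0.879
TBC1D10C	0.879
CD27	0.877
CD48	0.872
GZMK	0.870
SASH3	0.865
LY9	0.865
SEPT1	0.865
PTPRCAP	0.862
ARHGAP9	0.858
CD3G	0.857
TESPA1	0.856
MAP4K1	0.854
CORO1A	0.842
SLAMF1	0.841
NLRC3	0.839
CST7	0.838
IL2RG	0.838
WAS	0.837
CD8A	0.834
CD5	0.829
GIMAP5	0.828
IKZF1	0.828
ZAP70	0.828
KLRK1	0.827
CCL5	0.827
GPR171	0.826
PVRIG	0.825
PTPN7	0.824
CXCR6	0.823
EVI2B	0.823
CCR5	0.819
GZMA	0.815
ICOS	0.815
GRAP2	0.813
PTPRC	0.808
GIMAP4	0.806
PDCD1	0.806
CTLA4	0.727
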