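band_id,protein,peptide_matches,reported_trend
2,Unknown,12,increasing
3,Unknown,33,increasing
3,Unknown,34,increasing
5,NA,NA,decreasing
6,NA,NA,decreasing
10,NA,NA,decreasing
14,Unknown,39,decreasing
14,Unknown,36,decreasing
22,RhoGAP (LbGAP),52,decreasing
22,Unknown,21,decreasing
22,Serpin (LbSPNm),17,decreasing
22,RhoGAP (LbGAPy),11,decreasing
23,NA,NA,decreasing
27,RhoGAP (LbGAP2),20,decreasing
27,Unknown,18,decreasing
30,Unknown,19,increasing
35,NA,NA,increasing
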