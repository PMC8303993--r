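band_id,protein,peptide_matches,reported_trend
1,NA,NA,increasing
10,Unknown,10,increasing
10,Unknown,10,increasing
11,NA,NA,decreasing
16,Unknown,16,decreasing
18,Serpin (LbSPNy),81,decreasing
19,Serpin (LbSPNy),81,increasing
21,Unknown,25,increasing
24,RhoGAP (LbGAPy4),24,increasing
28,Unknown,20,decreasing
28,RhoGAP (LbGAPy2),17,decreasing
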