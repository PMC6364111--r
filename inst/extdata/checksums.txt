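edb9157821aaf4d4c73fea7428aa92cc  table2_calibration.csv
852a2c7a82417aa1fae265050b796291  table3_rcf.csv
1b96d0bb1048179d98feb4184809524b  table4_contents.csv
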