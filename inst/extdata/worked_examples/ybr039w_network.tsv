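protein_a	protein_b	combined_score
YBR039W	YBL099W	999
YBR039W	YDL004W	999
YBR039W	YDR298C	999
YBR039W	YLR295C	917
YBR039W	YML081C-A	934
YBR039W	YPL078C	999
YBR039W	YPL271W	997
YBR039W	YPR024W	986
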