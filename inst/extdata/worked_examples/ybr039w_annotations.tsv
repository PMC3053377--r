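YBR039W	4
YBL099W	4
YDL004W	4
YDR298C	4
YLR295C	4
YML081C-A	4,5
YPL078C	4
YPL271W	4
YPR024W	4,5,1
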