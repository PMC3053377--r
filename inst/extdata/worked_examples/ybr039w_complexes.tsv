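YBR039W	C1
YBL099W	C1
YDL004W	C1
YDR298C	C1,C2
YLR295C	C1
YML081C-A	C1
YPL078C	C1,C2
YPL271W	C1
YPR024W	C3
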