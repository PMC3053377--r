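YDL028C	2,5
YBL084C	2,8
YDR168W	2
YGL116W	2
YGR113W	2,5
YGR188C	5
YIL106W	2,5
YKL022C	2,1
YKL042W	2
YMR055C	2
YOR026W	2,1
YPL209C	2,5,1
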