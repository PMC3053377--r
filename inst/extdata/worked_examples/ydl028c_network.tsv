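protein_a	protein_b	combined_score
YDL028C	YBL084C	929
YDL028C	YDR168W	999
YDL028C	YGL116W	956
YDL028C	YGR113W	999
YDL028C	YGR188C	999
YDL028C	YIL106W	988
YDL028C	YKL022C	929
YDL028C	YKL042W	990
YDL028C	YMR055C	984
YDL028C	YOR026W	978
YDL028C	YPL209C	984
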