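YDL028C	sce04111
YBL084C	sce04111,sce04113,sce04120
YDR168W	no annotation
YGL116W	sce04111,sce04113,sce04120
YGR113W	sce04111
YGR188C	sce04111,sce04113
YIL106W	sce04111
YKL022C	sce04111,sce04113,sce04120
YKL042W	no annotation
YMR055C	sce04111
YOR026W	sce04111
YPL209C	no annotation
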