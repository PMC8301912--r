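# Canonical PBMC subtype surface markers (cluster of differentiation).
CD3D
CD3E
CD4
CD8A
CD14
CD19
FCGR3A
NCAM1
PTPRC
ITGAM
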