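LOC_Os09g12750	G2-like
LOC_Os03g21240	G2-like
LOC_Os07g25710	G2-like
LOC_Os02g04640	G2-like
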