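gene_id	reason
rrn16Sa	ribosomal RNA operon A (editable template entry)
rrn23Sa	ribosomal RNA operon A (editable template entry)
rrn16Sb	ribosomal RNA operon B (editable template entry)
rrn23Sb	ribosomal RNA operon B (editable template entry)
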