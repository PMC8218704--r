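sample_type	n_assayed	n_single_droplet
plasma	27	5
CSF	9	2
serum	6	0
cyst	1	0
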