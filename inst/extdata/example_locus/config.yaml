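sequences: sequences.fa
snps: snps.tsv
junction_k: 12
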