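# Example blacklist for remove_blacklisted_genes(): one symbol per line.
# In a real analysis these would be cell-cycle, apoptosis and ribosomal
# protein gene symbols; here they name synthetic background genes.
gene_0001
gene_0002
gene_0003
gene_0010
gene_0025
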