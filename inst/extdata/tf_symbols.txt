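# Hair-cell transcription-factor symbols tracked by the synthetic generator;
# input format for filter_tf_genes(): one symbol per line.
Atoh1
Barhl1
Lhx3
Gata3
Hes6
Neurod6
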