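# Published out-of-sample confusion matrix of the RandNet classifier on the
# hESC test partition (columns = true class, rows = predicted class; class
# order: cell_cluster debris unattached_cell attached_cell dynamic_blebbing
# apoptotic_blebbing).
154 0 0 2 3 1
0 187 1 0 0 0
0 0 121 0 0 1
0 0 6 173 2 0
1 5 0 1 97 3
4 1 1 0 1 123
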