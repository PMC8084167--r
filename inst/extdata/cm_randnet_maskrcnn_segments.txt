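# Published confusion matrix of the RandNet classifier applied to crops
# segmented by Mask RCNN (columns = true class, rows = predicted class).
85 1 1 0 0 7
0 70 0 2 0 0
1 0 62 0 0 0
8 0 0 79 0 0
0 4 0 0 37 0
0 0 0 0 2 60
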