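>CTCF_SYN synthetic 19-bp CTCF-like motif (constructed stand-in, not the empirical JASPAR matrix)
A [   1   1 199   1   1 199   1   1   1   1   1   1   1   1   1 199   1   1   1 ]
C [ 199 199   1 199 199   1   1   1   1   1   1 199   1 199   1   1   1   1   1 ]
G [   1   1   1   1   1   1 199 199 199 199 199   1 199   1   1   1 199   1 199 ]
T [   1   1   1   1   1   1   1   1   1   1   1   1   1   1 199   1   1 199   1 ]
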