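>EX0001 exampleTF
A [ 0.8601695 0.0466102 0.0466102 0.8601695 0.0466102 0.0466102 0.0466102 0.8601695 ]
C [ 0.0466102 0.0466102 0.8601695 0.0466102 0.0466102 0.8601695 0.0466102 0.0466102 ]
G [ 0.0466102 0.8601695 0.0466102 0.0466102 0.0466102 0.0466102 0.8601695 0.0466102 ]
T [ 0.0466102 0.0466102 0.0466102 0.0466102 0.8601695 0.0466102 0.0466102 0.0466102 ]
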