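>wild-type
ATCCAAATTCCATTTTGTGGACCTGGCAGGATCAGAG
>i271
ATCCAAATTCCATTTTGTCAGGATCAGAGCGCATCCTTAA
>i272
ATCCAAATTCCATTCCTGGCAGGATCAGAGCGCATCCTTAAAACCGGCAACACCGGCGAACGGCTCAAG
GAGAGCATTCAGATCAACAGTGGACTTCTTGTTCTTGGAAATGTCATTGGAGCGCTTGGGGACCCCAAA
AGAAAAGGCACCCATATCCCATACAGGGATTCAAAAATCACCAGGATCTTAA
>i273
ATCCAAATTCCATTTTGTCCTGGCAGGATCAGAG
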