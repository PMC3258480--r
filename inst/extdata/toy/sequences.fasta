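>R1|A
MKTAHCDEFGHIKLMNPQRSTVWYACDEFG
>R2|A
AAADAAAAAACDEFGAAAAA
>R2|B
CCCCCKCCCCWYAACCCCCCDDDDDDDDDD
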