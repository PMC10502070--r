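>EFHG
GGCACAGCTTGGGAGACTTTACCAGCACTATCCATTTCGGCT
>fh
TAAAGTCTCCCAAGCAATGGATAGTGCTGG
>efh
TGTGCCTAAAGTCTCCCAAGCAATGGATAGTGCTGG
>fhg
TAAAGTCTCCCAAGCAATGGATAGTGCTGGAGCCGA
>efhg
TGTGCCTAAAGTCTCCCAAGCAATGGATAGTGCTGGAGCCGA
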