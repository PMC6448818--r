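>native_d3u
UGGUUCACGUCUGCUGCAGGUCUCUGACUCU
>off_box
UGGUUCACGUCUGCUGCAGCUCUCUGACUCU
>scrambled_d3u
UGGUUCACGUUCUUCAAGACGCUCUGACUCU
>minus_cug
UGGUUCACGUUCUUCACAGGUCUCUGACUCU
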