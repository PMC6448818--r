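>native_core
CUGCUGCAGGU
>off_box_core
CUGCUGCAGCU
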