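CK7:
- CD45
- CD8
Ecad:
- CD45
- CD8
CD45:
- CK7
- Ecad
CD8:
- CK7
- Ecad
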