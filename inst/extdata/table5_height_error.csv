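bin,ciit,msi
>=12.5,25,7
"[10.0, 12.5)",58,38
"[7.5, 10.0)",66,52
"[5.0, 7.5)",93,101
"[2.5, 5.0)",124,145
"[0, 2.5)",208,231
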