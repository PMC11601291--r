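>let-7 dme-let-7-5p miRBase-derived reference sequence (analysis input)
UGAGGUAGUAGGUUGUAUAGUU
>bantam dme-bantam-3p miRBase-derived reference sequence (analysis input)
UGAGAUCAUUUUGAAAGCUGAUU
>miR-184 dme-miR-184-3p miRBase-derived reference sequence (analysis input)
UGGACGGAGAACUGAUAAGGGC
>miR-11 dme-miR-11-3p miRBase-derived reference sequence (analysis input)
CAUCACAGUCUGAGUUCUUGC
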