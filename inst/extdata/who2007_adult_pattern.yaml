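# Adult amino acid scoring pattern (WHO/FAO/UNU 2007), mg per g protein.
source_label: WHO/FAO/UNU 2007 adult scoring pattern
His: 15
Ile: 30
Leu: 59
Lys: 45
SAA: 22
AAA: 38
Thr: 23
Trp: 6
Val: 39
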