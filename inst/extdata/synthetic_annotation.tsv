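id	genome	category	amino_acid	anticodon	segments
nuc-AlaAGC-1	nuclear	canonical	Ala	AGC	acceptor5:0-7;d_arm:7-26;ac_arm:26-43;var:43-48;t_arm:48-65;acceptor3:65-72;disc:72-73;cca:73-76
pla-ArgACG-2	plastid	canonical	Arg	ACG	acceptor5:0-7;d_arm:7-26;ac_arm:26-43;var:43-48;t_arm:48-65;acceptor3:65-72;disc:72-73;cca:73-76
mit-AsnGTT-3	mitochondrial	canonical	Asn	GTT	acceptor5:0-7;d_arm:7-26;ac_arm:26-43;var:43-48;t_arm:48-65;acceptor3:65-72;disc:72-73;cca:73-76
telem-1	mitochondrial	t_element	---		acceptor5:0-7;d_arm:7-26;ac_arm:26-43;var:43-48;t_arm:48-65;acceptor3:65-72;disc:72-73
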