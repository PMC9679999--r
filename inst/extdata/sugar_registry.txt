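# one sugar per line: canonical symbol, tab-separated aliases
Glc
Gal
Man
GlcNAc
GalNAc
ManNAc
Fuc
Neu5Ac	NeuAc
Neu5Gc	NeuGc
Neu5,9Ac2
KDN	Kdn
MurNAc
GlcA
IdoA
GalA
Xyl
Rha
Ara
GlcN
GalN
Rib
Kdo
Any
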