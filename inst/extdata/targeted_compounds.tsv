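compound	surrogate_standard	phenolic
Quinic acid	Quinic acid	no
Malic acid	Malic acid	no
Citric acid	Citric acid	no
Isocitric acid	Isocitric acid	no
Succinic acid	Succinic acid	no
Sorbitol	Sorbitol	no
Trihydroxyoctadecenoic acid (I)	Isocitric acid	no
Trihydroxyoctadecenoic acid (II)	Isocitric acid	no
Trihydroxyoctadecenoic acid (III)	Isocitric acid	no
Verbascoside	Verbascoside	yes
Hydroxy-verbascoside (I)	Verbascoside	yes
Hydroxy-verbascoside (II)	Verbascoside	yes
3,4-Dihydroxy-phenylglycol	3,4-Dihydroxy-phenylglycol	yes
Hydroxytyrosol	Hydroxytyrosol	yes
Hydroxytyrosol glucoside (I)	Hydroxytyrosol	yes
Hydroxytyrosol glucoside (II)	Hydroxytyrosol	yes
Tyrosol	Tyrosol	yes
Tyrosol glucoside	Tyrosol glucoside	yes
Oleuropein	Oleuropein	yes
Oleuropein isomer (I)	Oleuropein	yes
Oleuropein isomer (II)	Oleuropein	yes
Elenolic acid	Oleuropein	no
DEDA	Oleuropein	no
Hydroxy-DEDA	Oleuropein	no
DEDA hydrated (I)	Oleuropein	no
DEDA hydrated (II)	Oleuropein	no
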