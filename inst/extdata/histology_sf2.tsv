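histology	sf2	source
Larynx	0.45	bjork_eriksson
Base of tongue	0.40	girinsky
Nasopharynx	0.45	bjork_eriksson
Retromolar trigone	0.64	girinsky
Parotid	0.28	weichselbaum
Sarcoma	0.42	ruka
Melanoma	0.48	deacon
SCC	0.48	deacon
Adenocarcinoma	0.40	deacon
Osteosarcoma	0.42	fertil
Liposarcoma	0.24	ruka
Leiomyosarcoma	0.55	malaise
Colorectal	0.40	leith
Tonsil	0.38	girinsky
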