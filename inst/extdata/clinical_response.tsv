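histology	response	qualifier	source	delivery
Osteosarcoma	100	NA	mohiuddin_i	block
Liposarcoma	50	NA	mohiuddin_i	block
Leiomyosarcoma	100	NA	mohiuddin_i	block
Colorectal	100	NA	mohiuddin_i	block
Sarcoma	94	NA	mohiuddin_ii	block
SCC	92	NA	mohiuddin_ii	block
Melanoma	83	NA	mohiuddin_ii	block
Adenocarcinoma	69	NA	mohiuddin_ii	block
Sarcoma	83	NA	mohiuddin_iii	block
SCC	94	NA	mohiuddin_iii	block
Adenocarcinoma	94	NA	mohiuddin_iii	block
Melanoma	50	NA	mohiuddin_iii	block
SCC	100	NA	sathishkumar	block
Adenocarcinoma	90	>	sathishkumar	block
Melanoma	80	>	sathishkumar	block
SCC	93	NA	huhn	block
Parotid	NA	NA	penagaricano	MLC
Base of tongue	30	NA	penagaricano	MLC
Maxillary sinus	50	NA	penagaricano	MLC
Nasopharynx	100	NA	penagaricano	MLC
Retromolar trigone	100	NA	penagaricano	MLC
Larynx	100	NA	penagaricano	MLC
Tonsil	25	NA	penagaricano	MLC
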