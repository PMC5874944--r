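# Reference cell-line parameter sets: tumour radiosensitivity classes
# (alpha/beta = 10 Gy), standard late-responding normal tissue
# (alpha/beta = 2.5 Gy), and published per-histology SF2 values.
- {key: radiosensitive, name: Radiosensitive tumour, sf2: 0.2, alpha_beta: 10}
- {key: semisensitive,  name: Semisensitive tumour,  sf2: 0.4, alpha_beta: 10}
- {key: radioresistant, name: Radioresistant tumour, sf2: 0.5, alpha_beta: 10}
- {key: normal,         name: Normal tissue,         sf2: 0.4, alpha_beta: 2.5}
- {key: larynx,             name: Larynx,             sf2: 0.45, alpha_beta: 10}
- {key: base_of_tongue,     name: Base of tongue,     sf2: 0.40, alpha_beta: 10}
- {key: nasopharynx,        name: Nasopharynx,        sf2: 0.45, alpha_beta: 10}
- {key: retromolar_trigone, name: Retromolar trigone, sf2: 0.64, alpha_beta: 10}
- {key: parotid,            name: Parotid,            sf2: 0.28, alpha_beta: 10}
- {key: sarcoma,            name: Sarcoma,            sf2: 0.42, alpha_beta: 10}
- {key: melanoma,           name: Melanoma,           sf2: 0.48, alpha_beta: 10}
- {key: scc,                name: Squamous cell carcinoma, sf2: 0.48, alpha_beta: 10}
- {key: adenocarcinoma,     name: Adenocarcinoma,     sf2: 0.40, alpha_beta: 10}
- {key: osteosarcoma,       name: Osteosarcoma,       sf2: 0.42, alpha_beta: 10}
- {key: liposarcoma,        name: Liposarcoma,        sf2: 0.24, alpha_beta: 10}
- {key: leiomyosarcoma,     name: Leiomyosarcoma,     sf2: 0.55, alpha_beta: 10}
- {key: colorectal,         name: Colorectal,         sf2: 0.40, alpha_beta: 10}
- {key: tonsil,             name: Tonsil,             sf2: 0.38, alpha_beta: 10}
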