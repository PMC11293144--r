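types:
- {type: Gene_Expression, label: Gene Expression}
- {type: Transcription, label: Transcription}
- {type: Protein_Catabolism, label: Protein Catabolism}
- {type: Phosphorylation, label: Phosphorylation}
- {type: Localization, label: Localization}
- {type: Binding, label: Binding}
- {type: Regulation, label: Regulation}
- {type: Positive_Regulation, label: Positive Regulation}
- {type: Negative_Regulation, label: Negative Regulation}
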