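types:
- {type: Cell_Proliferation, label: Cell Proliferation}
- {type: Development, label: Development}
- {type: Blood_Vessel_Development, label: Blood Vessel Development}
- {type: Growth, label: Growth}
- {type: Death, label: Death}
- {type: Breakdown, label: Breakdown}
- {type: Remodeling, label: Remodeling}
- {type: Synthesis, label: Synthesis}
- {type: Gene_Expression, label: Gene Expression}
- {type: Transcription, label: Transcription}
- {type: Catabolism, label: Catabolism}
- {type: Phosphorylation, label: Phosphorylation}
- {type: Dephosphorylation, label: Dephosphorylation}
- {type: Localization, label: Localization}
- {type: Binding, label: Binding}
- {type: Regulation, label: Regulation}
- {type: Positive_Regulation, label: Positive Regulation}
- {type: Negative_Regulation, label: Negative Regulation}
- {type: Planned_Process, label: Planned Process}
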