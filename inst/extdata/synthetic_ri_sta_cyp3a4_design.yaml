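# Synthetic reversible-inhibition assay design (generated, not measured)
enzyme_target: CYP3A4
microsome_genotype: CYP3A5*3/*3
cyp3cide_conc: 0
protein_conc: 0.2
incubation_time: 10
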