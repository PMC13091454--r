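# Atomic solvation parameters, kcal mol^-1 A^-2 (Eisenberg & McLachlan 1986
# five-class set). Defaults from prior literature; override with your own
# TSV via asp_table(file=).
# version: 1
class	sigma
apolar_C	0.016
polar_N_O	-0.006
carboxylate_O_minus	-0.024
charged_N_plus	-0.050
sulfur	0.021
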