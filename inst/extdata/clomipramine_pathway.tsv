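From	To	Reaction Type	Controller	Compartment
clomipramine	desmethylclomipramine	Biochemical Reaction	CYP1A2, CYP2C19, CYP3A4	liver cell
clomipramine	2-hydroxyclomipramine	Biochemical Reaction	CYP2D6	liver cell
desmethylclomipramine	2-hydroxydesmethylclomipramine	Biochemical Reaction	CYP2D6	liver cell
desmethylclomipramine	didesmethylclomipramine	Biochemical Reaction	CYP2C19	liver cell
2-hydroxyclomipramine	2-hydroxyclomipramine glucuronide	Biochemical Reaction	UGT2B10	liver cell
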