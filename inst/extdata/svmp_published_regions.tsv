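antigen_id	start	end	label
P85420	4	6	predicted
P85420	11	19	predicted
P85420	27	34	predicted
P85420	78	82	predicted
P85420	126	135	predicted
P85420	152	155	predicted
P85420	164	167	predicted
P85420	179	182	predicted
P83512	13	18	predicted
P83512	39	44	predicted
P83512	49	52	predicted
P83512	77	86	predicted
P83512	161	169	predicted
P83512	176	188	predicted
P84907	11	24	predicted
P84907	38	48	predicted
P84907	78	84	predicted
P84907	114	130	predicted
P84907	147	168	predicted
P84907	176	183	predicted
P85420	19	39	epitope
P85420	46	75	epitope
P85420	78	88	reactive
P85420	137	147	reactive
P85420	163	167	reactive
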