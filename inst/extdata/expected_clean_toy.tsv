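allele	peptide	label
HLA-A*02:01	ALDKFYTSV	0
HLA-A*02:01	EEEEEEEE	0
HLA-A*02:01	HHHHHHHH	0
HLA-A*02:01	KVAELVHFL	1
HLA-A*02:01	LLLLLLLLL	1
HLA-A*02:01	SIINFEKL	1
HLA-B*35:01	GLCTLVAML	1
HLA-B*35:01	NLVPMVATV	0
HLA-B*35:01	PPPPPPPPP	1
HLA-B*35:01	RAKFKQLL	1
HLA-B*35:01	RRRRRRRRR	1
HLA-C*07:02	FLYALALLL	0
HLA-C*07:02	YLLEMLWRL	1
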