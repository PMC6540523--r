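peptide	allele	label	source
SIINFEKL	HLA-A*02:01	Positive	src1
ALDKFYTSV	HLA-A*02:01	Negative	src1
KVAELVHFL	HLA-A*02:01	Positive-High	src1
GLCTLVAML	HLA-B*35:01	Positive	src2
NLVPMVATV	HLA-B*35:01	Negative	src2
RAKFKQLL	hla-b*35:01	Positive	src2
YLLEMLWRL	HLA-C*07:02	Positive	src3
FLYALALLL	HLA-C*07:02:01:02	Negative	src3
TOOLONGPEPTIDEAB	HLA-A*02:01	Positive	src1
ACDEFG	HLA-A*02:01	Positive	src1
SIXNFEKLM	HLA-A*02:01	Positive	src1
ABCDEFGHI	HLA-A*02:01	Negative	src1
SIINFEKL	HLA-A30	Positive	src1
SIINFEKL	MHC class I	Positive	src1
GILGFVFTL	HLA-B27	Positive	src2
QQQQQQQQQ	HLA-A*02:01	Garbage	src1
WWWWWWWWW	HLA-A*02:01	Positive-Intermediate	src1
VVVVVVVVV	HLA-A*02:01	Positive-Low	src1
MMMMMMMMM	HLA-A*02:01	Positive	badsrc
DDDDDDDDD	HLA-B*35:01	Negative	badsrc
EEEEEEEE	HLA-A*02:01	Positive	badsrc
EEEEEEEE	HLA-A*02:01	Negative	src1
LLLLLLLLL	HLA-A*02:01	Positive	src1
LLLLLLLLL	HLA-A*02:01	Positive	src2
LLLLLLLLL	HLA-A*02:01	Positive	src3
LLLLLLLLL	HLA-A*02:01	Positive	src4
LLLLLLLLL	HLA-A*02:01	Positive	src5
RRRRRRRRR	HLA-B*35:01	Positive	src1
RRRRRRRRR	HLA-B*35:01	Positive	src2
RRRRRRRRR	HLA-B*35:01	Positive-High	src3
RRRRRRRRR	HLA-B*35:01	Negative	src4
TTTTTTTTT	HLA-C*07:02	Positive	src1
TTTTTTTTT	HLA-C*07:02	Positive	src2
TTTTTTTTT	HLA-C*07:02	Negative	src3
TTTTTTTTT	HLA-C*07:02	Negative	src4
HHHHHHHH	HLA-A*02:01	Negative	src1
HHHHHHHH	HLA-A*02:01	Negative	src2
HHHHHHHH	HLA-A*02:01	Positive	src3
KKKKKKKKK	HLA-C*07:02	Positive-Low	src1
PPPPPPPPP	HLA-B*35:01	Positive-High	src2
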