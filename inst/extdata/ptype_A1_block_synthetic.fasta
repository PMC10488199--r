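>AHA1_ARATH
GWVISAWKNQSLTAVRSAFDLFIFALLYNMT
>AHA2_ARATH
GWLISAWKNQSLTAVRSAFDLMIFALLYNMT
>PMA2_NICPL
GWAISAWKLQSLTAVRSAFDLEIFALLYWMT
>PMA1_ORYSJ
GWLIVAWKSQSLTAVRSAFDLMIFALHYEMT
>PMA1_YEAST
GFLQSASKDQSKTAVRSAEDLFIFPLLFNCT
>PMA1_NEUCR
GILIDAAKNLSMTAVRSSFDLIIFAELENMW
>SERCA1_RABIT
PFLE-CWWDQVLWAVRGAGDCMDCAGLLNIT
>ATNA_SQUAC
FWAV-HWENPLLTKVRNKFDMMDFTFLYQMF
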