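# SSRI generic and brand-name synonyms, CANONICAL<TAB>SYNONYM
fluoxetine	Prozac
fluoxetine	Sarafem
fluoxetine	Selfemra
citalopram	Celexa
citalopram	Cipramil
escitalopram	Lexapro
escitalopram	Cipralex
paroxetine	Paxil
paroxetine	Seroxat
paroxetine	Brisdelle
sertraline	Zoloft
sertraline	Lustral
fluvoxamine	Luvox
fluvoxamine	Faverin
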