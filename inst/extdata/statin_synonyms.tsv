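# Statin generic and brand-name synonyms, CANONICAL<TAB>SYNONYM
atorvastatin	Lipitor
simvastatin	Zocor
rosuvastatin	Crestor
pravastatin	Pravachol
lovastatin	Mevacor
fluvastatin	Lescol
pitavastatin	Livalo
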