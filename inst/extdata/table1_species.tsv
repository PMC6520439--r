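code	species	diet
Mn	Macrotermes natalensis	fungus
Od	Odontotermes sp.	fungus
Cu	Cubitermes ugandensis	soil
Aw	Amitermes wheeleri	dung
Nt	Neocapritermes taracua	humus
Th	Termes hospes	humus
Co	Cornitermes sp.	litter
Mp	Microcerotermes parvus	wood
Nc	Nasutitermes corniger	wood
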