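mock	species	concentration	group	role
Tpos1	Ephemerella ignita	0.2	Ephemeroptera	prey
Tpos1	Hydropsyche modesta	0.2	Trichoptera	prey
Tpos1	Oligoneuriella rhenana	0.2	Ephemeroptera	prey
Tpos1	Eisenia andrei	0.2	Oligochaeta	prey
Tpos1	Chironomus riparius	0.2	Diptera	prey
Tpos1	Dinocras cephalotes	0.2	Plecoptera	prey
Tpos1	Phoxinus cf. phoxinus	0.2	Cypriniformes	prey
Tpos1	Zingel asper	0.8	Perciformes	predator
Tpos2	Ephemerella ignita	0.2	Ephemeroptera	prey
Tpos2	Hydropsyche modesta	0.2	Trichoptera	prey
Tpos2	Chironomus riparius	0.2	Diptera	prey
Tpos2	Hydropsyche instabilis	0.2	Trichoptera	prey
Tpos2	Gammarus pulex	0.2	Crustacea	prey
Tpos2	Planorbarius corneus	0.2	Gastropoda	prey
Tpos2	Velia saulii	0.2	Heteroptera	prey
Tpos2	Zingel asper	0.8	Perciformes	predator
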