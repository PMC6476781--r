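predator	predator_group	n_samples	material	habitat	region
Zingel asper	Zingel asper	46	feces	freshwater	Palearctic
Pomatoschistus microps (Vaccares Lagoon)	Pomatoschistus microps	15	feces	brackish	Palearctic
Pomatoschistus microps (Prevost Lagoon)	Pomatoschistus microps	14	feces	brackish	Palearctic
Unknown bat species	bats	1	feces	terrestrial	Palearctic
Myotis nattereri	bats	2	feces	terrestrial	Palearctic
Pipistrellus pipistrellus	bats	1	feces	terrestrial	Palearctic
Eptesicus serotinus	bats	1	feces	terrestrial	Palearctic
Miniopterus schreibersii	bats	4	feces	terrestrial	Palearctic
Barbastella barbastellus	bats	1	feces	terrestrial	Palearctic
Rhinolophus euryale	bats	1	feces	terrestrial	Palearctic
Rhinolophus ferrumequinum	bats	1	feces	terrestrial	Palearctic
Myotis emarginatus	bats	1	feces	terrestrial	Palearctic
Epiplatys infrafasciatus	Epiplatys infrafasciatus	6	feces	freshwater	Equatorial
Unknown spider species	spider webs	3	spider web	terrestrial	Equatorial
Araneomorphae	spider webs	5	spider web	terrestrial	Equatorial
Pholcidae	spider webs	2	spider web	terrestrial	Equatorial
Micrathena schreibersi	spider webs	3	spider web	terrestrial	Equatorial
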