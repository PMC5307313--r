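# Occurrence counts of 40 discrete prey taxa in leopard cat (lpc, n = 93
# food-containing faecal samples) and Asiatic golden cat (agc, n = 10)
# diets from a montane forest study area in Southwest China, as recovered
# by 12S V5 faecal metabarcoding. rank is the taxonomic level of the
# assignment; taxon_order the containing order.
taxon	common_name	rank	taxon_order	lpc	agc
Niviventer confucianus	Chinese white-bellied rat	species	Rodentia	58	2
Apodemus draco	South China field mouse	species	Rodentia	41	0
Eothenomys chinensis	Sichuan Chinese vole	species	Rodentia	35	1
Niviventer excelsior	Large white-bellied rat	species	Rodentia	25	1
Eothenomys melanogaster	Pere David's vole	species	Rodentia	18	0
Apodemus chevrieri	Chevrier's field mouse	species	Rodentia	5	0
Leopoldamys edwardsi	Edwards's long-tailed giant rat	species	Rodentia	5	0
Trogopterus xanthipes	Complex-toothed flying squirrel	species	Rodentia	2	1
Rhizomys sinensis	Chinese bamboo rat	species	Rodentia	1	4
Sciurotamias davidianus	Chinese rock squirrel	species	Rodentia	1	1
Apodemus peninsulae	Korean field mouse	species	Rodentia	1	0
Hystrix brachyura	Malayan porcupine	species	Rodentia	1	0
Dremomys pernyi	Perny's long-nosed squirrel	species	Rodentia	0	1
Ochotona spp.	Pikas	genus	Lagomorpha	71	3
Carnivora indet.	Undetermined carnivore	order	Carnivora	27	2
Felidae indet.	Undetermined felid	family	Carnivora	1	0
Tragopan temminckii	Temminck's tragopan	species	Galliformes	15	6
Gallus gallus	Red jungle fowl	species	Galliformes	7	2
Chrysolophus pictus	Golden pheasant	species	Galliformes	3	0
Bambusicola thoracicus	Chinese bamboo partridge	species	Galliformes	1	0
Passeriformes indet.	Undetermined passerine	order	Passeriformes	8	1
Timaliidae	Old World babblers	family	Passeriformes	4	0
Prinia inornata	Plain prinia	species	Passeriformes	4	1
Turdidae	Thrushes	family	Passeriformes	2	1
Alcippe chrysotis	Golden-breasted fulvetta	species	Passeriformes	2	0
Yuhina spp.	Yuhinas	genus	Passeriformes	2	0
Episoriculus macrurus	Long-tailed mountain shrew	species	Soricomorpha	7	1
Sorex spp.	Shrews	genus	Soricomorpha	7	0
Scaptonyx fusicaudus	Long-tailed mole	species	Soricomorpha	3	0
Uropsilus soricipes	Chinese shrew mole	species	Soricomorpha	3	0
Soricinae	Red-toothed shrews	subfamily	Soricomorpha	1	0
Sus scrofa	Wild boar	species	Artiodactyla	9	2
Budorcas taxicolor	Takin	species	Artiodactyla	3	2
Naemorhedus griseus	Chinese goral	species	Artiodactyla	2	0
Moschus berezovskii	Forest musk deer	species	Artiodactyla	0	1
Rhinopithecus roxellana	Golden snub-nosed monkey	species	Primates	2	1
Macaca mulatta	Rhesus macaque	species	Primates	0	1
Anas spp.	Ducks	genus	Anseriformes	2	0
Plestiodon capito	Yellow-striped skink	species	Lacertiformes	1	0
Cyprinidae	Carps	family	Cypriniformes	1	0
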