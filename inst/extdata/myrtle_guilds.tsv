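label	key	rank	trophic_modes	guild
Ascomycota sp.	Ascomycota	phylum	Pathotroph-Saprotroph-Symbiotroph	All possible guilds
Aurantiporus sp. 1	Aurantiporus	genus	Saprotroph	Wood Saprotroph
Aurantiporus sp. 2	Aurantiporus	genus	Saprotroph	Wood Saprotroph
Botryobasidium sp.	Botryobasidium	genus	Saprotroph	Wood Saprotroph
Calocera sp.	Calocera	genus	Saprotroph	undefined Saprotroph
Candida sp.	Candida	genus	Saprotroph	Wood Saprotroph
Ceratastomella sp.	Ceratastomella	genus	Pathotroph-Saprotroph-Symbiotroph	Animal Pathogen-Endosymbiont-undefined Saprotroph
Ceratobasidium sp.	Ceratobasidium	genus	Pathotroph	Plant Pathogen
Chaetothyriales sp.	Chaetothyriales	order	Pathotroph-Saprotroph-Symbiotroph	Endomycorrhizal-Plant Pathogen-undefined Saprotroph
Dacrymyces sp.	Dacrymyces	genus	Pathothroph	Endosymbiont-Plant Pathogen-undefined Saprotroph
Filobasidium sp.	Filobasidium	genus	Saprotroph	Wood Saprotroph
Flagelloscypha sp.	Flagelloscypha	genus	Saprotroph	undefined Saprotroph
Ganoderma sp.	Ganoderma	genus	Saprotroph	undefined Saprotroph
Gloeoporus sp.	Gloeoporus	genus	Pathotroph-Saprotroph	Plant Pathogen-Wood Saprotroph
Gymnopilus sp. 1	Gymnopilus	genus	Saprotroph	Wood Saprotroph
Gymnopilus sp. 2	Gymnopilus	genus	Saprotroph	Wood Saprotroph
Gymnopilus sp. 3	Gymnopilus	genus	Saprotroph	Wood Saprotroph
Hymenochaetaceae sp.	Hymenochaetaceae	family	Saprotroph	Wood Saprotroph
Hymenochaetales sp. 1	Hymenochaetales	order	Saprotroph-Symbiotroph	Ectomycorrhizal-Wood Saprotroph
Hymenochaetales sp. 2	Hymenochaetales	order	Pathotroph-Saprotroph-Symbiotroph	Ectomycorrhizal-Wood Saprotroph-Plant Pathogen
Hymenochaetales sp. 3	Hymenochaetales	order	Pathotroph-Saprotroph-Symbiotroph	Ectomycorrhizal-Wood Saprotroph-Plant Pathogen
Hymenochaete sp.	Hymenochaete	genus	Pathotroph-Saprotroph-Symbiotroph	Ectomycorrhizal-Wood Saprotroph-Plant Pathogen
Hyphoderma sp.	Hyphoderma	genus	Saprotroph	undefined Saprotroph
Hyphodontia sp.	Hyphodontia	genus	Saprotroph	undefined Saprotroph
Malassezia sp. 1	Malassezia	genus	Saprotroph	undefined Saprotroph
Naganishia sp.	Naganishia	genus	Pathotroph-Saprotroph	Animal Pathogen-undefined Saprotroph
Neopestalotiopsis sp.	Neopestalotiopsis	genus	Pathotroph-Saprotroph-Symbiotroph	Animal Pathogen-Endophyte-Epiphyte-undefined Saprotroph
Phragmidium sp.	Phragmidium	genus	Pathotroph	Plant Pathogen
Physisporinus sp.	Physisporinus	genus	Saprotroph	undefined Saprotroph
Polyporaceae sp. 1	Polyporaceae	family	Saprotroph	Wood Saprotroph
Polyporaceae sp. 2	Polyporaceae	family	Saprotroph	Wood Saprotroph
Pterulaceae sp.	Pterulaceae	family	Saprotroph	Wood Saprotroph
Pycnoporus sp.	Pycnoporus	genus	Saprotroph	Wood Saprotroph
Rhodotorula sp.	Rhodotorula	genus	Saprotroph	Wood Saprotroph
Spegazzinia sp.	Spegazzinia	genus	Pathotroph-Saprotroph	Animal Endosymbiont-Animal Pathogen-Endophyte-Plant Pathogen-undefined Saprotroph
Sporobolomyces sp.	Sporobolomyces	genus	Saprotroph	undefined Saprotroph
Sympodiomycopsis sp.	Sympodiomycopsis	genus	Pathotroph-Saprotroph	Fungal Parasite-Litter Saprotroph
Thelephorales sp.	Thelephorales	order	Pathotroph	Plant Pathogen
Trametes sp. 1	Trametes	genus	Symbiotroph-Saprothroph	Ectosymbiont-Wood Saprotroph
Trametes sp. 2	Trametes	genus	Saprotroph	Wood Saprotroph
Trametes sp. 3	Trametes	genus	Saprotroph	Wood Saprotroph
Tricholomataceae sp.	Tricholomataceae	family	Saprotroph	Wood Saprotroph
Trichomerium sp.	Trichomerium	genus	Pathotroph-Symbiotroph	Ectomycorrhizal-Fungal Parasite
Tyromyces sp.	Tyromyces	genus	Symbiotroph	Endophyte
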