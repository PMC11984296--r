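scientific_name,common_name,group
Danio rerio,zebra danio,fish
Brachydanio rerio,zebra danio,fish
Oncorhynchus mykiss,rainbow trout,fish
Salmo gairdneri,rainbow trout,fish
Pimephales promelas,fathead minnow,fish
Lepomis macrochirus,bluegill,fish
Oryzias latipes,medaka,fish
Cyprinus carpio,common carp,fish
Carassius auratus,goldfish,fish
Poecilia reticulata,guppy,fish
Gasterosteus aculeatus,threespine stickleback,fish
Ictalurus punctatus,channel catfish,fish
Salvelinus fontinalis,brook trout,fish
Salmo trutta,brown trout,fish
Gambusia affinis,western mosquitofish,fish
Perca fluviatilis,european perch,fish
Esox lucius,northern pike,fish
Micropterus salmoides,largemouth bass,fish
Rutilus rutilus,roach,fish
Oreochromis niloticus,nile tilapia,fish
Tilapia nilotica,nile tilapia,fish
Leuciscus idus,ide,fish
Daphnia magna,water flea,crustaceans
Daphnia pulex,water flea,crustaceans
Ceriodaphnia dubia,water flea,crustaceans
Hyalella azteca,scud,crustaceans
Gammarus pulex,scud,crustaceans
Gammarus fasciatus,scud,crustaceans
Asellus aquaticus,aquatic sowbug,crustaceans
Procambarus clarkii,red swamp crayfish,crustaceans
Moina macrocopa,water flea,crustaceans
Thamnocephalus platyurus,fairy shrimp,crustaceans
Artemia salina,brine shrimp,crustaceans
Raphidocelis subcapitata,green algae,algae
Pseudokirchneriella subcapitata,green algae,algae
Selenastrum capricornutum,green algae,algae
Chlorella vulgaris,green algae,algae
Scenedesmus quadricauda,green algae,algae
Desmodesmus subspicatus,green algae,algae
Chlamydomonas reinhardtii,green algae,algae
Navicula pelliculosa,diatom,algae
Anabaena flos-aquae,blue-green algae,algae
Microcystis aeruginosa,blue-green algae,algae
Synechococcus leopoliensis,blue-green algae,algae
Lemna minor,duckweed,aquatic_plants
Lemna gibba,gibbous duckweed,aquatic_plants
Spirodela polyrhiza,giant duckweed,aquatic_plants
Myriophyllum spicatum,eurasian watermilfoil,aquatic_plants
Elodea canadensis,canadian waterweed,aquatic_plants
Ceratophyllum demersum,coontail,aquatic_plants
Chironomus riparius,midge,insects_spiders
Chironomus tentans,midge,insects_spiders
Chironomus dilutus,midge,insects_spiders
Aedes aegypti,yellow fever mosquito,insects_spiders
Culex pipiens,house mosquito,insects_spiders
Baetis rhodani,mayfly,insects_spiders
Hexagenia limbata,burrowing mayfly,insects_spiders
Lymnaea stagnalis,great pond snail,molluscs
Physella acuta,bladder snail,molluscs
Physa acuta,bladder snail,molluscs
Planorbella trivolvis,ramshorn snail,molluscs
Dreissena polymorpha,zebra mussel,molluscs
Corbicula fluminea,asian clam,molluscs
Potamopyrgus antipodarum,new zealand mud snail,molluscs
Biomphalaria glabrata,bloodfluke planorb,molluscs
Hydra attenuata,hydra,invertebrates
Hydra vulgaris,hydra,invertebrates
Brachionus calyciflorus,rotifer,invertebrates
Tubifex tubifex,sludge worm,invertebrates
Lumbriculus variegatus,blackworm,invertebrates
Dugesia japonica,planarian,invertebrates
Caenorhabditis elegans,roundworm,invertebrates
Xenopus laevis,african clawed frog,amphibians
Rana pipiens,northern leopard frog,amphibians
Lithobates pipiens,northern leopard frog,amphibians
Bufo bufo,common toad,amphibians
Ambystoma mexicanum,axolotl,amphibians
Aliivibrio fischeri,luminescent bacteria,other
Vibrio fischeri,luminescent bacteria,other
Tetrahymena thermophila,ciliate,other
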