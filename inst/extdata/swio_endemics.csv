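latin_binomial,common_name,order,family,cat_1980,cat_2005,cat_2020,newly_described,threat_codes,change_type
Squalus acutipinnis,Bluntnose Spurdog,Squaliformes,Squalidae,LC,LC,NT,TRUE,5;5.4;11,none
Squalus bassi,African Longnose Spurdog,Squaliformes,Squalidae,LC,LC,LC,TRUE,,none
Squalus lalannei,Seychelles Spurdog,Squaliformes,Squalidae,LC,LC,LC,FALSE,,non_genuine
Centrophorus seychellorum,Seychelles Gulper Shark,Squaliformes,Centrophoridae,LC,LC,LC,FALSE,,non_genuine
Etmopterus compagnoi,Brown Lanternshark,Squaliformes,Etmopteridae,LC,LC,LC,TRUE,,none
Etmopterus sculptus,Sculpted Lanternshark,Squaliformes,Etmopteridae,LC,LC,LC,TRUE,,none
Etmopterus sentosus,Thorny Lanternshark,Squaliformes,Etmopteridae,LC,LC,LC,FALSE,,none
Etmopterus alphus,Whitecheek Lanternshark,Squaliformes,Etmopteridae,LC,LC,LC,TRUE,,none
Pliotrema annae,Anna's Sixgill Sawshark,Pristiophoriformes,Pristiophoridae,DD,DD,DD,TRUE,,none
Pliotrema kajae,Kaja's Sixgill Sawshark,Pristiophoriformes,Pristiophoridae,DD,DD,DD,TRUE,,none
Pliotrema warreni,Warren's Sixgill Sawshark,Pristiophoriformes,Pristiophoridae,LC,LC,LC,TRUE,,none
Squatina africana,African Angelshark,Squatiniformes,Squatinidae,LC,LC,NT,FALSE,5;5.4;11,non_genuine
Chiloscyllium caeruleopunctatum,Bluespotted Bambooshark,Orectolobiformes,Hemiscylliidae,DD,DD,DD,TRUE,,none
Pseudoginglymostoma brevicaudatum,Shorttail Nurse Shark,Orectolobiformes,Ginglymostomatidae,LC,VU,CR,FALSE,5;5.4;11,genuine
Apristurus saldanha,Saldanha Catshark,Carcharhiniformes,Pentanchidae,LC,LC,LC,FALSE,,none
Bythaelurus clevai,Broadhead Catshark,Carcharhiniformes,Pentanchidae,DD,DD,DD,FALSE,,none
Bythaelurus lutarius,Mud Catshark,Carcharhiniformes,Pentanchidae,DD,DD,DD,TRUE,,none
Bythaelurus tenuicephalus,Narrowhead Catshark,Carcharhiniformes,Pentanchidae,LC,LC,LC,TRUE,,none
Halaelurus lineatus,Lined Catshark,Carcharhiniformes,Pentanchidae,LC,LC,LC,FALSE,,non_genuine
Halaelurus natalensis,Tiger Catshark,Carcharhiniformes,Pentanchidae,LC,NT,VU,FALSE,5;5.4;11,non_genuine
Haploblepharus edwardsii,Happy Eddie Catshark,Carcharhiniformes,Pentanchidae,LC,NT,EN,FALSE,5;5.4;1;9,non_genuine
Haploblepharus fuscus,Brown Shyshark,Carcharhiniformes,Pentanchidae,LC,VU,VU,FALSE,5;5.4;1;9,none
Haploblepharus kistnasamyi,Natal Shyshark,Carcharhiniformes,Pentanchidae,LC,NT,VU,FALSE,5;5.4;1;9,non_genuine
Haploblepharus pictus,Dark Shyshark,Carcharhiniformes,Pentanchidae,LC,LC,LC,FALSE,,none
Holohalaelurus favus,Honeycomb Izak Catshark,Carcharhiniformes,Pentanchidae,LC,EN,EN,FALSE,5;5.4,none
Holohalaelurus grennian,Grinning Izak Catshark,Carcharhiniformes,Pentanchidae,DD,DD,DD,FALSE,,none
Holohalaelurus melanostigma,Crying Izak Catshark,Carcharhiniformes,Pentanchidae,LC,LC,LC,FALSE,,non_genuine
Holohalaelurus punctatus,African Spotted Catshark,Carcharhiniformes,Pentanchidae,LC,EN,EN,FALSE,5;5.4,none
Holohalaelurus regani,Izak Catshark,Carcharhiniformes,Pentanchidae,LC,LC,LC,FALSE,,none
Cephaloscyllium sufflans,Balloon Shark,Carcharhiniformes,Scyliorhinidae,LC,LC,NT,FALSE,5;5.4,non_genuine
Poroderma africanum,Pyjama Shark,Carcharhiniformes,Scyliorhinidae,LC,LC,LC,FALSE,,non_genuine
Poroderma pantherinum,Leopard Catshark,Carcharhiniformes,Scyliorhinidae,LC,LC,LC,FALSE,,non_genuine
Scyliorhinus capensis,Yellowspotted Catshark,Carcharhiniformes,Scyliorhinidae,LC,LC,NT,FALSE,5;5.4,none
Scyliorhinus comoroensis,Comoro Catshark,Carcharhiniformes,Scyliorhinidae,DD,DD,DD,FALSE,,none
Eridacnis sinuans,African Ribbontail Catshark,Carcharhiniformes,Proscyllidae,LC,LC,LC,FALSE,,none
Mustelus palumbes,Whitespotted Smoothhound,Carcharhiniformes,Triakidae,LC,LC,LC,FALSE,,non_genuine
Scylliogaleus quecketti,Flapnose Houndshark,Carcharhiniformes,Triakidae,LC,NT,VU,FALSE,5;5.4,none
Triakis megalopterus,Spotted Gully Shark,Carcharhiniformes,Triakidae,LC,LC,LC,FALSE,,non_genuine
Narcine insolita,Madagascar Numbfish,Torpediniformes,Narcinidae,DD,DD,DD,FALSE,,none
Electrolux addisoni,Ornate Sleeper Ray,Torpediniformes,Narkidae,LC,LC,LC,FALSE,,non_genuine
Heteronarce garmani,Natal Sleeper Ray,Torpediniformes,Narkidae,NT,NT,NT,FALSE,5;5.4,non_genuine
Narke capensis,Cape Sleeper Ray,Torpediniformes,Narkidae,LC,LC,LC,FALSE,,non_genuine
Tetronarce cowleyi,South African Torpedo,Torpediniformes,Torpedinidae,LC,LC,LC,TRUE,,none
Torpedo fuscomaculata,Blackspotted Torpedo,Torpediniformes,Torpedinidae,DD,DD,DD,FALSE,,none
Acroteriobatus annulatus,Lesser Guitarfish,Rhinopristiformes,Rhinobatidae,LC,NT,VU,FALSE,5;5.4;11,non_genuine
Acroteriobatus blochii,Bluntnose Guitarfish,Rhinopristiformes,Rhinobatidae,LC,LC,LC,FALSE,,none
Acroteriobatus leucospilus,Greyspot Guitarfish,Rhinopristiformes,Rhinobatidae,LC,VU,EN,FALSE,5;5.4;11,non_genuine
Acroteriobatus ocellatus,Speckled Guitarfish,Rhinopristiformes,Rhinobatidae,DD,DD,DD,FALSE,,none
Rhinobatos austini,Austin's Guitarfish,Rhinopristiformes,Rhinobatidae,DD,DD,DD,TRUE,,none
Rhinobatos holcorhynchus,Slender Guitarfish,Rhinopristiformes,Rhinobatidae,DD,DD,DD,FALSE,,none
Dipturus campbelli,Blackspot Skate,Rajiformes,Rajidae,LC,LC,NT,FALSE,5;5.4,none
Dipturus crosnieri,Madagascar Skate,Rajiformes,Rajidae,LC,VU,VU,FALSE,5;5.4,none
Dipturus lanceorostratus,Rattail Skate,Rajiformes,Rajidae,DD,DD,DD,FALSE,,none
Dipturus pullopunctatus,Slime Skate,Rajiformes,Rajidae,LC,LC,LC,FALSE,,none
Dipturus stenorhynchus,Prownose Skate,Rajiformes,Rajidae,DD,DD,DD,FALSE,,none
Leucoraja compagnoi,Tigertail Skate,Rajiformes,Rajidae,DD,DD,DD,FALSE,,none
Leucoraja wallacei,Yellowspotted Skate,Rajiformes,Rajidae,LC,LC,VU,FALSE,5;5.4,non_genuine
Neoraja stehmanni,South African Dwarf Skate,Rajiformes,Rajidae,LC,LC,LC,FALSE,,non_genuine
Okamejei heemstrai,Narrow Skate,Rajiformes,Rajidae,LC,LC,LC,FALSE,,non_genuine
Raja ocellifera,Twineye Skate,Rajiformes,Rajidae,LC,VU,EN,TRUE,5;5.4;11,none
Rajella caudaspinosa,Munchkin Skate,Rajiformes,Rajidae,LC,LC,LC,FALSE,,non_genuine
Rajella paucispinosa,Sparsethorn Skate,Rajiformes,Rajidae,LC,LC,LC,TRUE,,none
Bathyraja smithii,Softnose Skate,Rajiformes,Arhynchobatidae,LC,LC,LC,FALSE,,non_genuine
Cruriraja durbanensis,Smoothnose Pygmy Skate,Rajiformes,Gurgesiellidae,DD,DD,DD,FALSE,,none
Cruriraja hulleyi,Hulley's Pygmy Skate,Rajiformes,Gurgesiellidae,LC,LC,LC,FALSE,,none
Cruriraja parcomaculata,Roughnose Pygmy Skate,Rajiformes,Gurgesiellidae,LC,LC,LC,FALSE,,non_genuine
Fenestraja maceachrani,Madagascar Pygmy Skate,Rajiformes,Gurgesiellidae,DD,DD,DD,FALSE,,none
Anacanthobatis marmorata,Spotted Legskate,Rajiformes,Anacanthobatidae,LC,LC,NT,FALSE,5;5.4,non_genuine
Indobatis ori,Black Legskate,Rajiformes,Anacanthobatidae,LC,LC,LC,FALSE,,non_genuine
Gymnura natalensis,Diamond Ray,Myliobatiformes,Gymnuridae,LC,LC,LC,FALSE,,non_genuine
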