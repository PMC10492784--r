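stage,series,period,max_ma,min_ma,international
Kasimovian,Pennsylvanian,Carboniferous,307.0,303.7,TRUE
Gzhelian,Pennsylvanian,Carboniferous,303.7,298.9,TRUE
Asselian,Cisuralian,Permian,298.9,293.5,TRUE
Sakmarian,Cisuralian,Permian,293.5,290.1,TRUE
Artinskian,Cisuralian,Permian,290.1,283.5,TRUE
Kungurian,Cisuralian,Permian,283.5,273.0,TRUE
Roadian,Guadalupian,Permian,273.0,266.9,TRUE
Wordian,Guadalupian,Permian,266.9,264.3,TRUE
Capitanian,Guadalupian,Permian,264.3,259.5,TRUE
Wuchiapingian,Lopingian,Permian,259.5,254.1,TRUE
Changhsingian,Lopingian,Permian,254.1,251.9,TRUE
Induan,Lower Triassic,Triassic,251.9,249.9,TRUE
Olenekian,Lower Triassic,Triassic,249.9,247.2,TRUE
Anisian,Middle Triassic,Triassic,247.2,242.0,TRUE
Ladinian,Middle Triassic,Triassic,242.0,237.0,TRUE
Carnian,Upper Triassic,Triassic,237.0,227.0,TRUE
Norian,Upper Triassic,Triassic,227.0,208.5,TRUE
Rhaetian,Upper Triassic,Triassic,208.5,201.4,TRUE
Hettangian,Lower Jurassic,Jurassic,201.4,199.5,TRUE
Sinemurian,Lower Jurassic,Jurassic,199.5,192.9,TRUE
Pliensbachian,Lower Jurassic,Jurassic,192.9,184.2,TRUE
Toarcian,Lower Jurassic,Jurassic,184.2,174.7,TRUE
Aalenian,Middle Jurassic,Jurassic,174.7,170.9,TRUE
Bajocian,Middle Jurassic,Jurassic,170.9,168.2,TRUE
Bathonian,Middle Jurassic,Jurassic,168.2,165.3,TRUE
Callovian,Middle Jurassic,Jurassic,165.3,161.5,TRUE
Oxfordian,Upper Jurassic,Jurassic,161.5,154.8,TRUE
Kimmeridgian,Upper Jurassic,Jurassic,154.8,149.2,TRUE
Tithonian,Upper Jurassic,Jurassic,149.2,143.1,TRUE
Berriasian,Lower Cretaceous,Cretaceous,143.1,137.7,TRUE
Valanginian,Lower Cretaceous,Cretaceous,137.7,132.6,TRUE
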