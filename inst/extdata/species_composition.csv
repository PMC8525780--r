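species,Brazil_2012_2013,Panama_2016_2017,Panama_2020
Albizia adinocephala,,4,
Anacardium excelsum,,4,
Annona spraguei,,,1
Apeiba membranacea,,5,2
Aspidosperma spruceanum,,,5
Bixa orellana,,,1
Brosimum utile,,,11
Calycophyllum candidissimum,,3,
Carapa guianensis,,3,1
Castilla elastica,,1,
Cecropia insignis,,,17
Cecropia obtusifolia,,,1
Cespedesia spathulata,,,1
Chamaecrista xinguensis,12,,
Clusia rosea,,,2
Cordia alliodora,,4,
Cupania scrobiculata,,,1
Dendropanax arboreus,,,2
Erisma uncinatum,24,,
Ficus insipida,,5,
Guatteria dumetorum,,23,7
Inga multijuga,,,2
Lonchocarpus heptaphyllus,,,1
Luehea seemannii,,5,1
Manilkara bidentata,,,1
Manilkara elata,3,,
Manilkara zapota,,,3
Maranthes panamensis,,,1
Marila laxiflora,,,1
Melastomacea family,,,6
Mezilaurus itauba,5,,
Miconia minutiflora,,29,1
Pera arborea,,,3
Persea americana,,,1
Philodendron fragrantissimum,,,3
Philodendron grandipes,,,2
Pittoniotis trichantha,,4,
Pourouma bicolor,,,1
Protium panamense,,,2
Salacia multiflora,,,1
Sloanea meianthera,,,1
Symphonia globulifera,,,2
Tachigali cf. chrysophylla,1,,
Tachigali versicolor,,7,2
Tapirira guianensis,,,12
Terminalia amazonia,,21,
Tocoyena pittieri,,10,
Tovomita longifolia,,,3
Tovomita stylosa,,,4
Virola elata,,,1
Virola multiflora,,,1
Vochysia ferruginea,,17,1
Xylopia macrantha,,,2
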