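"record_id","collection_id","taxon_name","gbif_id","rank","stage","subbasin","paleolat","paleolon","lat_modern","lon_modern","depth_class","t_min_c","t_max_c"
"Pragian_Taxon_0001_r01","Pragian_Taxon_0001_c01","Taxon_0001",1000001,"genus","Pragian","Kharaulakh",14.3222018461674,116.642508488148,39.3222018461674,110.078795235604,"deep",20.6,23
"Pragian_Taxon_0001_r02","Pragian_Taxon_0001_c02","Taxon_0001",1000001,"genus","Pragian","Kharaulakh",11.5833333376795,107.691829414107,36.5833333376795,122.4158905074,"deep",20.6,23
"Pragian_Taxon_0001_r03","Pragian_Taxon_0001_c03","Taxon_0001",1000001,"genus","Pragian","Kharaulakh",10.8556266985834,118.481273856014,35.8556266985834,90.2843615226448,"deep",20.6,23
"Pragian_Taxon_0001_r04","Pragian_Taxon_0001_c04","Taxon_0001",1000001,"genus","Pragian","Kharaulakh",11.048093884252,80.9453046368435,36.048093884252,90.5877564381808,"deep",20.6,23
"Pragian_Taxon_0002_r01","Pragian_Taxon_0002_c01","Taxon_0002",1000002,"genus","Pragian","Verkhoyansk",33.8285751296207,119.334129332565,58.8285751296207,115.004869187251,"shallow",15.4,18.3
"Pragian_Taxon_0002_r02","Pragian_Taxon_0002_c02","Taxon_0002",1000002,"genus","Pragian","Verkhoyansk",34.8138423254713,96.8371745757759,59.8138423254713,100.412001414225,"shallow",15.4,18.3
"Pragian_Taxon_0002_r03","Pragian_Taxon_0002_c03","Taxon_0002",1000002,"genus","Pragian","Verkhoyansk",32.1965662324801,102.611143807881,57.1965662324801,124.362924713641,"shallow",15.4,18.3
"Pragian_Taxon_0002_r04","Pragian_Taxon_0002_c04","Taxon_0002",1000002,"genus","Pragian","Verkhoyansk",34.3424002202228,106.20167139452,59.3424002202228,107.499520080164,"shallow",15.4,18.3
"Pragian_Taxon_0002_r05","Pragian_Taxon_0002_c05","Taxon_0002",1000002,"genus","Pragian","Verkhoyansk",34.2384770894423,113.21904942859,59.2384770894423,105.525790303946,"shallow",15.4,18.3
"Pragian_Taxon_0003_r01","Pragian_Taxon_0003_c01","Taxon_0003",1000003,"genus","Pragian","Tunguska",27.7790578138083,76.5420615999028,52.7790578138083,97.3869385290891,"shallow",17.9,19.5
"Pragian_Taxon_0003_r02","Pragian_Taxon_0003_c02","Taxon_0003",1000003,"genus","Pragian","Tunguska",26.8077541664243,78.6228658491746,51.8077541664243,97.3349291272461,"shallow",17.9,19.5
"Pragian_Taxon_0003_r03","Pragian_Taxon_0003_c03","Taxon_0003",1000003,"genus","Pragian","Tunguska",26.196795434691,62.5305315619335,51.196795434691,120.218496657908,"shallow",17.9,19.5
"Pragian_Taxon_0004_r01","Pragian_Taxon_0004_c01","Taxon_0004",1000004,"genus","Pragian","Vilyui",10.8743157433346,94.3611002108082,35.8743157433346,91.0020142607391,"shallow",20.6,23
"Pragian_Taxon_0004_r02","Pragian_Taxon_0004_c02","Taxon_0004",1000004,"genus","Pragian","Vilyui",13.1934554642066,81.0385544970632,38.1934554642066,106.044041514397,"shallow",20.6,23
"Pragian_Taxon_0004_r03","Pragian_Taxon_0004_c03","Taxon_0004",1000004,"genus","Pragian","Vilyui",11.332647758536,100.319935698062,36.332647758536,97.9990611970425,"shallow",20.6,23
"Pragian_Taxon_0005_r01","Pragian_Taxon_0005_c01","Taxon_0005",1000005,"genus","Pragian","Nordvik",44.1796735571697,80.4040944110602,69.1796735571697,112.415505209938,"shallow",13.9,18.7
"Pragian_Taxon_0005_r02","Pragian_Taxon_0005_c02","Taxon_0005",1000005,"genus","Pragian","Nordvik",44.6396352676675,118.605311075225,69.6396352676675,108.55232716538,"shallow",13.9,18.7
"Pragian_Taxon_0005_r03","Pragian_Taxon_0005_c03","Taxon_0005",1000005,"genus","Pragian","Nordvik",42.0484633008018,83.8209847128019,67.0484633008018,97.8710730653256,"shallow",13.9,18.7
"Pragian_Taxon_0005_r04","Pragian_Taxon_0005_c04","Taxon_0005",1000005,"genus","Pragian","Nordvik",43.6863392870873,82.7999327564612,68.6863392870873,107.077736109495,"shallow",13.9,18.7
"Pragian_Taxon_0006_r01","Pragian_Taxon_0006_c01","Taxon_0006",1000006,"genus","Pragian","Kharaulakh",41.1110990960151,86.4018992520869,66.1110990960151,107.105562910438,"shallow",13.4,14.9
"Pragian_Taxon_0006_r02","Pragian_Taxon_0006_c02","Taxon_0006",1000006,"genus","Pragian","Kharaulakh",41.2002348536626,72.0560837723315,66.2002348536626,129.223999269307,"shallow",13.4,14.9
"Pragian_Taxon_0007_r01","Pragian_Taxon_0007_c01","Taxon_0007",1000007,"genus","Pragian","Verkhoyansk",11.4820475708693,113.938316772692,36.4820475708693,95.1470793038607,"shallow",22.4,23.4
"Pragian_Taxon_0007_r02","Pragian_Taxon_0007_c02","Taxon_0007",1000007,"genus","Pragian","Verkhoyansk",9.314254488796,87.2026200173423,34.314254488796,90.9862535074353,"shallow",22.4,23.4
"Pragian_Taxon_0007_r03","Pragian_Taxon_0007_c03","Taxon_0007",1000007,"genus","Pragian","Verkhoyansk",10.5500266561285,68.845066758804,35.5500266561285,119.452454997227,"shallow",22.4,23.4
"Pragian_Taxon_0008_r01","Pragian_Taxon_0008_c01","Taxon_0008",1000008,"genus","Pragian","Tunguska",37.8313868828118,109.519680803642,62.8313868828118,124.907853612676,"shallow",15.6,17.2
"Pragian_Taxon_0008_r02","Pragian_Taxon_0008_c02","Taxon_0008",1000008,"genus","Pragian","Tunguska",38.6354603869841,108.821740429848,63.6354603869841,94.422195982188,"shallow",15.6,17.2
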