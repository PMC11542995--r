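zone,depth,t_min_c,t_max_c,lat_min,lat_max,note
tropical,shallow,20,35,0,25,"equatorial/tropical shallow habitat temperatures"
subtropical,shallow,18,25,25,35,"subtropical shallow; overlaps tropical over 20-25 C"
warm_temperate,shallow,12,20,35,50,"middle latitudes; 10-12 C gap below is preserved"
cool_temperate,shallow,4,10,50,65,"high latitudes"
polar,shallow,0,4,65,90,"polar shallow"
tropical,deep,5,12,0,25,"below the 250-300 m cutoff; upper bound ~12 C, operational lower bound 5 C"
warm_temperate,deep,5,7,35,50,"mid-latitude deep water"
cool_temperate,deep,1,4,50,65,"high-latitude deep water"
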