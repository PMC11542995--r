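alias,stage
Visean (Vise),Visean
Tournasian,Tournaisian
Gzelian,Gzhelian
Changxingian,Changhsingian
Wujiapingian,Wuchiapingian
Olenyokian,Olenekian
Pragien,Pragian
Sakmarskian,Sakmarian
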