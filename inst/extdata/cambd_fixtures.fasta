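>Tau-R2 start=287
VQSKCGSKDNIKHVPGGG
>CaMKIIA start=296
RRKLKGAILTTMLATR
>GSK3beta-CaMBD1 start=81
LVAIKKVLQDKRFKNRELQI
>GSK3beta-CaMBD2 start=134
YVPETVYRVARHYSRAKQTLPVIY
>GSK3beta-CaMBD3 start=193
TAVLKLCDFGSAKQLVRGEPNV
>Cdk5-CaMBD1 start=17
GTVFKAKNRETHEIVALKRVALKRV
>Cdk5-CaMBD2 start=133
LINRNGELKLADFGLARAFG
>ROCK1-CaMBD1 start=86
AFGEVQLVRHKSTRKVYAM
>ROCK1-CaMBD2 start=1133
IKRYGWKKQYVVVSSKKIL
>CN-CaMBD start=391
ARKEVIRNKIRAIGKMARVFSVLR
>TGM2-CaMBD1 start=414
KSINRSLIVGLKISTKSVGR
>TGM2-CaMBD2 start=665
VVNFESDKLKAVKGFRNVII
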