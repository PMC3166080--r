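rank,treatment_id,compound,log2_ratio,agg_p,morph_p
1,camptothecin_biomol2,Camptothecin,-1.637238,0.00000365,0.151249
2,camptothecin_prestwick,Camptothecin,-1.22608,0.00000927,0.109087
3,camptothecin_ninds,Camptothecin,-1.152003,0.00000000,0.06008
4,etoposide_prestwick,Etoposide,-0.881592,0.00003212,0.003217
5,oh_camptothecin_biomol2,10-OH-Camptothecin,-2.21028,0.00000012,0.00242
6,ouabain_biomol2,Ouabain,-1.050767,0.00000268,0.000246
7,proscillaridin_a_prestwick,Proscillaridin A,-0.876806,0.00020794,0.000006
8,ethacrynic_acid_prestwick,Ethacrynic acid,-1.088665,0.00003454,0.000001
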