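"name","pattern","anchor","forbidden","linker"
"lewis_a","Galb1-3(Fuca1-4)GlcNAc","terminal","",
"lewis_x","Galb1-4(Fuca1-3)GlcNAc","terminal","",
"lewis_b","Fuca1-2Galb1-3(Fuca1-4)GlcNAc","terminal","",
"lewis_y","Fuca1-2Galb1-4(Fuca1-3)GlcNAc","terminal","",
"blood_group_H","Fuca1-2Gal","terminal","",
"bgH_type1","Fuca1-2Galb1-3GlcNAc","terminal","",
"bgH_type2","Fuca1-2Galb1-4GlcNAc","terminal","",
"bgH_type3","Fuca1-2Galb1-3GalNAc","terminal","",
"blood_group_A","GalNAca1-3(Fuca1-2)Gal","terminal","",
"blood_group_B","Gala1-3(Fuca1-2)Gal","terminal","",
"alpha_gal","Gala1-3Gal","terminal","2:extension:2",
"forssman","GalNAca1-3GalNAc","terminal","",
"lacnac_type1","Galb1-3GlcNAc","anywhere","",
"lacnac_type2","Galb1-4GlcNAc","anywhere","",
"lacdinac","GalNAcb1-4GlcNAc","terminal","",
"polylacnac_2","Galb1-4GlcNAcb1-3Galb1-4GlcNAc","anywhere","",
"polylacnac_3","Galb1-4GlcNAcb1-3Galb1-4GlcNAcb1-3Galb1-4GlcNAc","anywhere","",
"bisecting_glcnac","GlcNAcb1-4Manb1-4GlcNAc","terminal","",
"core_fucose","Fuca1-6GlcNAc","root","",
"antenna_fucose","Fuca1-3GlcNAc","anywhere","",
"chitobiose","GlcNAcb1-4GlcNAc","anywhere","",
"chitin_4","GlcNAcb1-4GlcNAcb1-4GlcNAcb1-4GlcNAc","anywhere","",
"n_core_man3","Mana1-6(Mana1-3)Manb1-4GlcNAcb1-4GlcNAc","anywhere","",
"high_man5","Mana1-6(Mana1-3)Mana1-6(Mana1-3)Manb1-4GlcNAcb1-4GlcNAc","anywhere","",
"high_man9","Mana1-2Mana1-6(Mana1-2Mana1-3)Mana1-6(Mana1-2Mana1-2Mana1-3)Manb1-4GlcNAcb1-4GlcNAc","anywhere","",
"terminal_man_a2","Mana1-2Man","terminal","",
"terminal_man_a3","Mana1-3Man","terminal","",
"terminal_man_a6","Mana1-6Man","terminal","",
"terminal_glcnac_b","GlcNAcb1-?Any","terminal","",
"terminal_glcnac_a","GlcNAca1-?Any","terminal","",
"terminal_galnac_a","GalNAca1-?Any","terminal","",
"terminal_galnac_b","GalNAcb1-?Any","terminal","",
"terminal_gal_b","Galb1-?Any","terminal","",
"terminal_gal_a","Gala1-?Any","terminal","",
"sialyl_a23","Neu5Aca2-3Any","anywhere","",
"sialyl_a26","Neu5Aca2-6Any","anywhere","",
"sialyl_a28","Neu5Aca2-8Neu5Ac","anywhere","",
"neu5gc","Neu5Gc","anywhere","",
"kdn","KDN","anywhere","",
"sulfo_3","(3S)Any","anywhere","",
"sulfo_3_gal","(3S)Gal","anywhere","",
"sulfo_6","(6S)Any","anywhere","",
"tn_antigen","GalNAc","root","1:extension:3|1:extension:6","Ser|Thr"
"core1_T","Galb1-3GalNAc","root","","Ser|Thr"
"core2","Galb1-3(GlcNAcb1-6)GalNAc","root","","Ser|Thr"
"core3","GlcNAcb1-3GalNAc","root","","Ser|Thr"
"core4","GlcNAcb1-3(GlcNAcb1-6)GalNAc","root","","Ser|Thr"
"sialyl_tn","Neu5Aca2-6GalNAc","root","","Ser|Thr"
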