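phenolic,water_solubility,caco2,intestinal_absorption,skin_logkp,bbb_logbb,cns_logps,max_tolerated_dose,hepatotoxic,skin_sensitizer,tpyriformis,minnow_loglc50
Resveratrol,-3.192,1.191,89.057,-3.16,-0.041,-2.098,0.486,No,No,1.072,0.342
Curcumin,-4.208,0.55,85.652,-2.744,-0.992,-2.959,-0.219,No,No,0.372,-0.631
Quercetin,-3.17,0.162,74.535,-2.735,-1.461,-3.374,0.983,No,No,0.317,0.943
Epigallocatechin gallate,-2.893,-0.721,58.337,-2.735,-2.363,-4.407,0.473,No,No,0.285,3.239
Genistein,-3.415,1.019,93.39,-2.737,-0.979,-2.156,0.709,No,No,0.528,5.12
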