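phenolic,mol_weight,alogp,rotatable_bonds,psa,hba,hbd,ro5_violations,aromatic_rings
Resveratrol,228.25,2.97,2,60.69,3,3,0,2
Curcumin,368.39,3.85,7,96.22,6,3,0,2
Quercetin,302.24,1.99,1,131.36,7,5,0,3
Epigallocatechin gallate,458.38,2.23,3,197.37,11,8,2,3
Genistein,270.24,2.58,1,90.9,5,3,0,3
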