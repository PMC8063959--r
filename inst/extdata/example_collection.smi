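# Tiny demonstration collection: SMILES <space> ID
OCC1OC(Oc2ccccc2)C(O)C(O)C1O phenyl-glucoside
OCC1OC(OCc2ccc(C)cc2)C(O)C(O)C1O methylbenzyl-glucoside
OCC1OC(OC2C(O)C(O)C(O)OC2CO)C(O)C(O)C1O maltose
OCC1(O)OC(CO)C(O)C1O fructose
OCC(O)C(O)C(O)CC=O deoxyglucose-open
OCC(O)C1OC(=O)C(O)=C1O vitamin-c
OC1C(O)C(O)C(O)C(O)C1O inositol
Cc1ccccc1 toluene
CC(C)Cc1ccc(C(C)C(=O)O)cc1 ibuprofen
O=C(OCC1OC(Oc2ccccc2OC3OC(COC(=O)c4ccccc4)C(O)C(O)C3O)C(O)C1O)c1ccccc1 bridged-diglycoside
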