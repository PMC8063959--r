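# Small illustrative sugar-moiety library (synthetic examples, not the
# curated bacterial glycoside dataset): SMILES <space> ID
OC[C@H]1OC(O)[C@H](O)[C@@H](O)[C@@H]1O glucopyranose_D
OC[C@@H]1OC(O)[C@@H](O)[C@H](O)[C@H]1O glucopyranose_L
OC[C@H]1OC(O)[C@H](O)[C@@H](O)[C@H]1O galactopyranose_D
CC1OC(O)CC(O)C1O didesoxyhexose_1
CC1OC(O)C(O)C(O)C1O desoxyhexose_1
OCC1OC(O)C(O)C1O ribofuranose_1
OCC1(O)OC(CO)C(O)C1O fructofuranose_1
OCC1OCC(O)C1O lowoxy_furanose_1
OC1CCCOC1O lowoxy_pyranose_1
OCC1OC(O)C(=O)C(O)C1O ketohexose_1
OCC1OC(O)C(O)C(O)C1N aminohexose_1
OCC1OC(O)C(O)C(O)C1O glucopyranose_flat
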