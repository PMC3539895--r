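name	smiles
ethanol	CCO
acetic acid	CC(=O)O
sodium acetate	CC(=O)[O-].[Na+]
glycine	NCC(=O)O
d-alanine	C[C@@H](N)C(=O)O
2-hydroxypyridine	Oc1ccccn1
neopentane	CC(C)(C)C
d-glucose	OC[C@H]1OC(O)[C@H](O)[C@@H](O)[C@@H]1O
sodium l-lactate	C[C@H](O)C(=O)[O-].[Na+]
l-lactic acid	C[C@H](O)C(=O)O
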