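variant_smiles,canonical_smiles
c1ccc(cc1)P(c1ccccc1)(c1ccccc1)[Pd],c1ccc(cc1)P(c1ccccc1)(c1ccccc1)[Pd](P(c1ccccc1)(c1ccccc1)c1ccccc1)(P(c1ccccc1)(c1ccccc1)c1ccccc1)P(c1ccccc1)(c1ccccc1)c1ccccc1
c1ccc(cc1)P(c1ccccc1)(c1ccccc1)[Pd]P(c1ccccc1)(c1ccccc1)c1ccccc1,c1ccc(cc1)P(c1ccccc1)(c1ccccc1)[Pd](P(c1ccccc1)(c1ccccc1)c1ccccc1)(P(c1ccccc1)(c1ccccc1)c1ccccc1)P(c1ccccc1)(c1ccccc1)c1ccccc1
[Pd].c1ccc(cc1)P(c1ccccc1)c1ccccc1,c1ccc(cc1)P(c1ccccc1)(c1ccccc1)[Pd](P(c1ccccc1)(c1ccccc1)c1ccccc1)(P(c1ccccc1)(c1ccccc1)c1ccccc1)P(c1ccccc1)(c1ccccc1)c1ccccc1
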