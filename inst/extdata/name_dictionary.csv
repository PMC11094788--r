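name,smiles
water,O
ethanol,CCO
methanol,CO
isopropanol,CC(C)O
tetrahydrofuran,C1CCOC1
thf,C1CCOC1
dichloromethane,ClCCl
dcm,ClCCl
methylene chloride,ClCCl
chloroform,ClC(Cl)Cl
acetonitrile,CC#N
mecn,CC#N
toluene,Cc1ccccc1
benzene,c1ccccc1
"n,n-dimethylformamide",CN(C)C=O
dmf,CN(C)C=O
dimethyl sulfoxide,CS(C)=O
dmso,CS(C)=O
acetic acid,CC(=O)O
ethyl acetate,CCOC(C)=O
acetone,CC(C)=O
diethyl ether,CCOCC
"1,2-dimethoxyethane",COCCOC
dme,COCCOC
"1,4-dioxane",C1COCCO1
dioxane,C1COCCO1
hexane,CCCCCC
cyclohexane,C1CCCCC1
pyridine,c1ccncc1
triethylamine,CCN(CC)CC
sulfuric acid,OS(=O)(=O)O
hydrochloric acid,Cl
sodium hydroxide,[Na+].[OH-]
potassium carbonate,O=C([O-])[O-].[K+].[K+]
sodium carbonate,O=C([O-])[O-].[Na+].[Na+]
palladium,[Pd]
palladium on carbon,[Pd]
"tetrakis(triphenylphosphine)palladium",c1ccc(cc1)P(c1ccccc1)(c1ccccc1)[Pd](P(c1ccccc1)(c1ccccc1)c1ccccc1)(P(c1ccccc1)(c1ccccc1)c1ccccc1)P(c1ccccc1)(c1ccccc1)c1ccccc1
sodium borohydride,[Na+].[BH4-]
p-toluenesulfonic acid,Cc1ccc(cc1)S(=O)(=O)O
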