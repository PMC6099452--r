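chemical,class,synonym_of
metformin,metformin,
glibenclamide,sulphonylurea,
gliclazide,sulphonylurea,
glimepiride,sulphonylurea,
glipizide,sulphonylurea,
tolbutamide,sulphonylurea,
chlorpropamide,sulphonylurea,
gliquidone,sulphonylurea,
pioglitazone,TZD,
rosiglitazone,TZD,
troglitazone,TZD,
sitagliptin,DPP4,
vildagliptin,DPP4,
saxagliptin,DPP4,
linagliptin,DPP4,
alogliptin,DPP4,
exenatide,GLP1,
liraglutide,GLP1,
lixisenatide,GLP1,
dulaglutide,GLP1,
albiglutide,GLP1,
dapagliflozin,SGLT2,
canagliflozin,SGLT2,
empagliflozin,SGLT2,
acarbose,other,
nateglinide,other,
repaglinide,other,
guar gum,other,
glyburide,,glibenclamide
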