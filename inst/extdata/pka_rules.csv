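name,type,smarts,pka,atom,max_sites
sulfonic_acid,acid,[SX4](=O)(=O)[OX2H1],-1.0,3,0
sulfinic_acid,acid,[SX3](=O)[OX2H1],2.0,2,0
phosphonic_acid_1,acid,[PX4](=O)[OX2H1],2.0,2,1
phosphonic_acid_2,acid,[PX4](=O)([OX1-])[OX2H1],7.2,3,0
carboxylic_acid,acid,[CX3](=O)[OX2H1],4.8,2,0
tetrazole,acid,[nX3H1]1nnnc1,4.9,0,0
aryl_thiol,acid,[SX2H1][c],6.6,0,0
imide,acid,[NX3H1](C(=O))C(=O),9.6,0,0
aliphatic_thiol,acid,[SX2H1][CX4],8.5,0,0
phenol,acid,[OX2H1][c],10.0,0,0
guanidine,base,[NX2]=[CX3]([NX3])[NX3],13.6,0,0
amidine,base,[NX2]=[CX3][NX3],12.4,0,0
aliphatic_amine,base,"[NX3;H2,H1,H0;+0;!$(NC=[O,S,N]);!$(N[a]);!$(N=*);!$(NS=O);!$(NO);!$(NN)]",10.7,0,0
pyridine,base,[nX2H0],5.2,0,0
aniline,base,"[NX3;H2,H1;+0][a]",4.6,0,0
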