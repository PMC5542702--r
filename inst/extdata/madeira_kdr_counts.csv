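locus,population,phenotype_class,n_wildtype_hom,n_het,n_mutant_hom
V1016I,Funchal,Cyfluthrin resistant,20,10,2
V1016I,Funchal,Cyfluthrin susceptible,15,4,0
V1016I,Funchal,Permethrin resistant,21,11,0
V1016I,Funchal,Permethrin susceptible,6,2,0
V1016I,Funchal,all,62,27,2
V1016I,Paul do Mar,Cyfluthrin resistant,6,5,1
V1016I,Paul do Mar,Cyfluthrin susceptible,21,15,0
V1016I,Paul do Mar,Permethrin resistant,18,11,1
V1016I,Paul do Mar,Permethrin susceptible,0,2,0
V1016I,Paul do Mar,all,45,33,2
F1534C,Funchal,all,0,0,91
F1534C,Paul do Mar,all,0,0,80
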