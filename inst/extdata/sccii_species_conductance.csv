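species,functional_group,gmin,gmin_se,gmin_n_trees,gmax,gmax_se,gmax_n_trees
Acer,angiosperm,4.8,0.4,5,275.7,20.4,4
Carpinus,angiosperm,1.2,0.1,5,149.6,11.9,4
Fagus,angiosperm,2.5,0.2,5,178.7,28.7,4
Fraxinus,angiosperm,2.9,0.4,3,225.2,6.5,3
Quercus,angiosperm,2.7,0.1,5,373.4,58.0,4
Sorbus,angiosperm,4.8,NA,2,369.7,NA,2
Abies,gymnosperm,1.5,0.2,4,114.6,7.2,4
Picea,gymnosperm,1.5,0.1,5,146.7,30.3,4
Pinus,gymnosperm,0.8,0.1,5,158.1,18.4,4
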