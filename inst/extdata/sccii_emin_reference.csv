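species,r_leaf_basal,e_std_32.2,e_std_35,e_std_40,e_tree_32.2,e_tree_35,e_tree_40
Acer,611.0,33.3,49.8,97.8,3.3,5.0,9.8
Carpinus,1046.6,24.6,34.9,62.1,1.5,2.1,3.7
Fagus,1161.3,36.7,50.5,85.6,2.2,3.0,5.1
Fraxinus,379.5,23.1,33.6,62.8,0.7,1.0,1.9
Quercus,401.9,21.1,30.7,57.5,5.3,7.7,14.4
Sorbus,406.3,30.9,45.0,84.2,2.8,4.1,7.6
Abies,274.2,6.9,10.6,21.9,0.3,0.4,0.9
Picea,836.8,13.8,19.0,32.3,1.0,1.3,2.3
Pinus,96.1,2.0,2.7,4.3,0.4,0.5,0.8
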