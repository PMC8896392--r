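class,Ribosomes,Cytosol,Nucleus,Cell membrane,Microfilaments,Mitochondria,Endoplasmic reticulum,Extracellular,Cell-ECM junctions,Golgi apparatus,Proteasome,Other vesicles,"Cilia, centrosome",Cell-cell junctions,Lysosomes,Peroxisomes,Focal adhesion sites,Cell cortex,UNKNOWN
Ribosomes,1,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
Cytosol,1,1,1,1,1,1,1,0,0,1,1,1,1,0,1,1,1,1,0
Nucleus,0,1,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
Cell membrane,0,1,0,1,1,0,0,1,1,0,0,0,0,1,0,0,1,1,0
Microfilaments,0,1,0,1,1,0,0,0,0,0,0,0,1,1,0,0,1,1,0
Mitochondria,0,1,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0
Endoplasmic reticulum,0,1,0,0,0,0,1,0,0,1,0,0,0,0,0,0,0,0,0
Extracellular,0,0,0,1,0,0,0,1,1,0,0,0,0,1,0,0,0,0,0
Cell-ECM junctions,0,0,0,1,0,0,0,1,1,0,0,0,0,0,0,0,0,0,0
Golgi apparatus,0,1,0,0,0,0,1,0,0,1,0,1,0,0,0,0,0,0,0
Proteasome,0,1,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0
Other vesicles,0,1,0,0,0,0,0,0,0,1,0,1,0,0,1,0,0,0,0
"Cilia, centrosome",0,1,0,0,1,0,0,0,0,0,0,0,1,0,0,0,0,0,0
Cell-cell junctions,0,0,0,1,1,0,0,1,0,0,0,0,0,1,0,0,0,0,0
Lysosomes,0,1,0,0,0,0,0,0,0,0,0,1,0,0,1,0,0,0,0
Peroxisomes,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0
Focal adhesion sites,0,1,0,1,1,0,0,0,0,0,0,0,0,0,0,0,1,0,0
Cell cortex,0,1,0,1,1,0,0,0,0,0,0,0,0,0,0,0,0,1,0
UNKNOWN,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1
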