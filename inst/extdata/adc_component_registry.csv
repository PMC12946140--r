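drug_name,brand_name,antibody,linker,payload,dar_value,dar_class,include
gemtuzumab ozogamicin,mylotarg,IgG4,cleavable,dna_damaging,2.5,lt3,TRUE
brentuximab vedotin,adcetris,IgG1,cleavable,microtubule_inhibitor,4,3to5,TRUE
ado-trastuzumab emtansine,kadcyla,IgG1,non_cleavable,microtubule_inhibitor,3.5,3to5,TRUE
inotuzumab ozogamicin,besponsa,IgG4,cleavable,dna_damaging,6,gt5,TRUE
moxetumomab pasudotox,lumoxiti,IgG1,cleavable,other,1,lt3,TRUE
polatuzumab vedotin,polivy,IgG1,cleavable,microtubule_inhibitor,3.5,3to5,TRUE
enfortumab vedotin,padcev,IgG1,cleavable,microtubule_inhibitor,3.8,3to5,TRUE
fam-trastuzumab deruxtecan,enhertu,IgG1,cleavable,dna_damaging,8,gt5,TRUE
sacituzumab govitecan,trodelvy,IgG1,cleavable,dna_damaging,7.6,gt5,TRUE
belantamab mafodotin,blenrep,IgG1,non_cleavable,microtubule_inhibitor,4,3to5,TRUE
loncastuximab tesirine,zynlonta,IgG1,cleavable,dna_damaging,2.3,lt3,TRUE
tisotumab vedotin,tivdak,IgG1,cleavable,microtubule_inhibitor,4,3to5,TRUE
mirvetuximab soravtansine,elahere,IgG1,cleavable,microtubule_inhibitor,3.4,3to5,TRUE
datopotamab deruxtecan,datroway,IgG1,cleavable,dna_damaging,4,3to5,FALSE
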