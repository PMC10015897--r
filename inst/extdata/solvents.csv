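name,et30_kcal_mol,dielectric,dipole_debye,aliases,source
toluene,33.9,2.38,0.36,methylbenzene;phme,Reichardt 2003 Table 7-3
benzene,34.3,2.27,0.00,,Reichardt 2003 Table 7-3
chloroform,39.1,4.81,1.04,trichloromethane;chcl3,Reichardt 2003 Table 7-3
dichloromethane,40.7,8.93,1.60,dcm;methylene chloride;ch2cl2,Reichardt 2003 Table 7-3
tetrahydrofuran,37.4,7.58,1.75,thf,Reichardt 2003 Table 7-3
"1,4-dioxane",36.0,2.25,0.45,dioxane,Reichardt 2003 Table 7-3
methanol,55.4,32.70,1.70,meoh,Reichardt 2003 Table 7-3
ethanol,51.9,24.55,1.69,etoh,Reichardt 2003 Table 7-3
acetonitrile,45.6,35.94,3.92,mecn;acn,Reichardt 2003 Table 7-3
dimethyl sulfoxide,45.1,46.45,3.96,dmso,Reichardt 2003 Table 7-3
"n,n-dimethylformamide",43.2,36.71,3.82,dmf,Reichardt 2003 Table 7-3
water,63.1,78.36,1.85,h2o,Reichardt 2003 Table 7-3
n-hexane,31.0,1.88,0.09,hexane,Reichardt 2003 Table 7-3
cyclohexane,30.9,2.02,0.00,,Reichardt 2003 Table 7-3
acetone,42.2,20.56,2.88,propanone,Reichardt 2003 Table 7-3
ethyl acetate,38.1,6.02,1.78,etoac,Reichardt 2003 Table 7-3
diethyl ether,34.5,4.20,1.15,ether;et2o,Reichardt 2003 Table 7-3
pyridine,40.5,12.91,2.19,,Reichardt 2003 Table 7-3
tetrachloromethane,32.4,2.24,0.00,carbon tetrachloride;ccl4,Reichardt 2003 Table 7-3
chlorobenzene,36.8,5.62,1.69,phcl,Reichardt 2003 Table 7-3
"n,n-dimethylacetamide",42.9,37.78,3.72,dmac;dma,Reichardt 2003 Table 7-3
1-butanol,49.7,17.51,1.66,n-butanol;butanol,Reichardt 2003 Table 7-3
2-propanol,48.4,19.92,1.56,isopropanol;ipa,Reichardt 2003 Table 7-3
dichloroethane,41.3,10.36,1.83,"1,2-dichloroethane;dce",Reichardt 2003 Table 7-3
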