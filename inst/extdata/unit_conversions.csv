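text,gas,basis,prefix,area,time,factor
Mg CH4-C ha-1 h-1,CH4,element,Mg,ha-1,h-1,8760000
g CH4 m-2 yr-1,CH4,molecule,g,m-2,yr-1,7.5
g CH4-C m-2 h-1,CH4,element,g,m-2,h-1,87600
g CH4-C m-2 yr-1,CH4,element,g,m-2,yr-1,10
kg CH4 ha-1 yr-1,CH4,molecule,kg,ha-1,yr-1,0.75
kg CH4-C ha-1 yr-1,CH4,element,kg,ha-1,yr-1,1
mg CH4 m-2 d-1,CH4,molecule,mg,m-2,d-1,2.7375000000000003
mg CH4 m-2 h-1,CH4,molecule,mg,m-2,h-1,65.7
mg CH4-C m-2 h-1,CH4,element,mg,m-2,h-1,87.60000000000001
mmol CH4 m-2 h-1,CH4,mol,mmol,m-2,h-1,1051.2
nmol CH4 m-2 s-1,CH4,mol,nmol,m-2,s-1,3.7843200000000006
t CO2-eq ha-1 yr-1,CH4,co2_equivalent,t,ha-1,yr-1,1000
ug CH4-C m-2 h-1,CH4,element,ug,m-2,h-1,0.08760000000000001
ug CH4-C m-2 s-1,CH4,element,ug,m-2,s-1,315.36
µg CH4–C m−2 h−1,CH4,element,ug,m-2,h-1,0.08760000000000001
Mg CO2-C ha-1 yr-1,CO2,element,Mg,ha-1,yr-1,1000
g CO2 C m-2 yr-1,CO2,element,g,m-2,yr-1,10
g CO2 m-2 d-1,CO2,molecule,g,m-2,d-1,995.4545454545455
g CO2 m-2 yr-1,CO2,molecule,g,m-2,yr-1,2.7272727272727275
g CO2-C m-2 h-1,CO2,element,g,m-2,h-1,87600
g CO2-C m-2 yr-1,CO2,element,g,m-2,yr-1,10
mg CO2-C m-2 h-1,CO2,element,mg,m-2,h-1,87.60000000000001
t CO2 ha-1 yr-1,CO2,molecule,t,ha-1,yr-1,272.72727272727275
t CO2-C ha-1 yr-1,CO2,element,t,ha-1,yr-1,1000
t CO2-eq ha-1 yr-1,CO2,co2_equivalent,t,ha-1,yr-1,1000
ug CO2-C m-2 h-1,CO2,element,ug,m-2,h-1,0.08760000000000001
g N2O m-2 yr-1,N2O,molecule,g,m-2,yr-1,6.363636363636364
g N2O-N m-2 yr-1,N2O,element,g,m-2,yr-1,10
kg N ha-1 yr-1,N2O,element,kg,ha-1,yr-1,1
kg N2O-N ha-1 yr-1,N2O,element,kg,ha-1,yr-1,1
mg N2O m-2 d-1,N2O,molecule,mg,m-2,d-1,2.3227272727272728
mg N2O m-2 yr-1,N2O,molecule,mg,m-2,yr-1,0.006363636363636364
mg N2O-N m-2 d-1,N2O,element,mg,m-2,d-1,3.65
mg N2O-N m-2 h-1,N2O,element,mg,m-2,h-1,87.60000000000001
mg N2O-N m-2 yr-1,N2O,element,mg,m-2,yr-1,0.01
nmol N2O-N m-2 s-1,N2O,mol,nmol,m-2,s-1,8.83008
t CO2-eq ha-1 yr-1,N2O,co2_equivalent,t,ha-1,yr-1,1000
ug N2O-N m-2 h-1,N2O,element,ug,m-2,h-1,0.08760000000000001
ug N2O-N m-2 s-1,N2O,element,ug,m-2,s-1,315.36
umol N2O m-2 h-1,N2O,mol,umol,m-2,h-1,2.4528
µg N2O–N m−2 h−1,N2O,element,ug,m-2,h-1,0.08760000000000001
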