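api,temperature_c,drug_load_wtpc,row,quantity,value,units,tolerance,tolerance_class
naproxen,37,10,dry,Tg,94.6,degC,1.5,gordon_taylor
naproxen,37,10,egt,water,9.3,wtpc,0.5,gordon_taylor
naproxen,37,10,egt,api,9.1,wtpc,0.5,gordon_taylor
naproxen,37,10,egt,polymer,81.6,wtpc,0.5,gordon_taylor
naproxen,37,10,egt,Tg,37.0,degC,1.5,gordon_taylor
naproxen,37,10,solubility,water,16.3,wtpc,1.0,pcsaft
naproxen,37,10,solubility,api,8.4,wtpc,1.0,pcsaft
naproxen,37,10,solubility,polymer,75.3,wtpc,1.0,pcsaft
naproxen,37,10,solubility,Tg,5.1,degC,3.0,pcsaft
naproxen,37,10,binodal-polymer-rich,water,31.0,wtpc,1.0,pcsaft
naproxen,37,10,binodal-polymer-rich,api,6.9,wtpc,1.0,pcsaft
naproxen,37,10,binodal-polymer-rich,polymer,62.1,wtpc,1.0,pcsaft
naproxen,37,10,binodal-polymer-rich,Tg,-42.6,degC,3.0,pcsaft
naproxen,37,10,binodal-api-rich,water,11.0,wtpc,1.0,pcsaft
naproxen,37,10,binodal-api-rich,api,35.2,wtpc,1.0,pcsaft
naproxen,37,10,binodal-api-rich,polymer,53.8,wtpc,1.0,pcsaft
naproxen,37,10,binodal-api-rich,Tg,3.2,degC,3.0,pcsaft
naproxen,37,20,dry,Tg,79.5,degC,1.5,gordon_taylor
naproxen,37,20,egt,water,7.3,wtpc,0.5,gordon_taylor
naproxen,37,20,egt,api,18.5,wtpc,0.5,gordon_taylor
naproxen,37,20,egt,polymer,74.2,wtpc,0.5,gordon_taylor
naproxen,37,20,egt,Tg,37.0,degC,1.5,gordon_taylor
naproxen,37,20,solubility,water,6.1,wtpc,1.0,pcsaft
naproxen,37,20,solubility,api,18.8,wtpc,1.0,pcsaft
naproxen,37,20,solubility,polymer,75.1,wtpc,1.0,pcsaft
naproxen,37,20,solubility,Tg,43.2,degC,3.0,pcsaft
naproxen,37,20,binodal-polymer-rich,water,22.1,wtpc,1.0,pcsaft
naproxen,37,20,binodal-polymer-rich,api,15.6,wtpc,1.0,pcsaft
naproxen,37,20,binodal-polymer-rich,polymer,62.3,wtpc,1.0,pcsaft
naproxen,37,20,binodal-polymer-rich,Tg,-22.1,degC,3.0,pcsaft
naproxen,37,20,binodal-api-rich,water,15.5,wtpc,1.0,pcsaft
naproxen,37,20,binodal-api-rich,api,23.2,wtpc,1.0,pcsaft
naproxen,37,20,binodal-api-rich,polymer,61.3,wtpc,1.0,pcsaft
naproxen,37,20,binodal-api-rich,Tg,-4.1,degC,3.0,pcsaft
naproxen,37,30,dry,Tg,65.7,degC,1.5,gordon_taylor
naproxen,37,30,egt,water,5.2,wtpc,0.5,gordon_taylor
naproxen,37,30,egt,api,28.4,wtpc,0.5,gordon_taylor
naproxen,37,30,egt,polymer,66.3,wtpc,0.5,gordon_taylor
naproxen,37,30,egt,Tg,37.0,degC,1.5,gordon_taylor
naproxen,37,30,solubility,flag,NA,supersaturated_dry,NA,pcsaft
naproxen,37,30,binodal-polymer-rich,water,24.4,wtpc,1.0,pcsaft
naproxen,37,30,binodal-polymer-rich,api,11.2,wtpc,1.0,pcsaft
naproxen,37,30,binodal-polymer-rich,polymer,64.4,wtpc,1.0,pcsaft
naproxen,37,30,binodal-polymer-rich,Tg,-26.3,degC,3.0,pcsaft
naproxen,37,30,binodal-api-rich,water,14.0,wtpc,1.0,pcsaft
naproxen,37,30,binodal-api-rich,api,25.8,wtpc,1.0,pcsaft
naproxen,37,30,binodal-api-rich,polymer,60.2,wtpc,1.0,pcsaft
naproxen,37,30,binodal-api-rich,Tg,-0.7,degC,3.0,pcsaft
venetoclax,37,0.5,dry,Tg,111.0,degC,1.5,gordon_taylor
venetoclax,37,0.5,egt,water,11.2,wtpc,0.5,gordon_taylor
venetoclax,37,0.5,egt,api,0.4,wtpc,0.5,gordon_taylor
venetoclax,37,0.5,egt,polymer,88.4,wtpc,0.5,gordon_taylor
venetoclax,37,0.5,egt,Tg,37.0,degC,1.5,gordon_taylor
venetoclax,37,0.5,solubility,flag,NA,supersaturated_dry,NA,pcsaft
venetoclax,37,0.5,binodal-polymer-rich,water,20.5,wtpc,1.0,pcsaft
venetoclax,37,0.5,binodal-polymer-rich,api,0.6,wtpc,1.0,pcsaft
venetoclax,37,0.5,binodal-polymer-rich,polymer,78.9,wtpc,1.0,pcsaft
venetoclax,37,0.5,binodal-polymer-rich,Tg,-4.4,degC,3.0,pcsaft
venetoclax,37,0.5,binodal-api-rich,water,0.6,wtpc,1.0,pcsaft
venetoclax,37,0.5,binodal-api-rich,api,99.4,wtpc,1.0,pcsaft
venetoclax,37,0.5,binodal-api-rich,polymer,0.0,wtpc,1.0,pcsaft
venetoclax,37,0.5,binodal-api-rich,Tg,113.9,degC,3.0,pcsaft
venetoclax,37,1,dry,Tg,111.1,degC,1.5,gordon_taylor
venetoclax,37,1,egt,water,11.2,wtpc,0.5,gordon_taylor
venetoclax,37,1,egt,api,0.9,wtpc,0.5,gordon_taylor
venetoclax,37,1,egt,polymer,87.9,wtpc,0.5,gordon_taylor
venetoclax,37,1,egt,Tg,37.0,degC,1.5,gordon_taylor
venetoclax,37,1,solubility,flag,NA,supersaturated_dry,NA,pcsaft
venetoclax,37,1,binodal-polymer-rich,water,15.6,wtpc,1.0,pcsaft
venetoclax,37,1,binodal-polymer-rich,api,0.9,wtpc,1.0,pcsaft
venetoclax,37,1,binodal-polymer-rich,polymer,83.5,wtpc,1.0,pcsaft
venetoclax,37,1,binodal-polymer-rich,Tg,15.8,degC,3.0,pcsaft
venetoclax,37,1,binodal-api-rich,water,0.4,wtpc,1.0,pcsaft
venetoclax,37,1,binodal-api-rich,api,99.6,wtpc,1.0,pcsaft
venetoclax,37,1,binodal-api-rich,polymer,0.0,wtpc,1.0,pcsaft
venetoclax,37,1,binodal-api-rich,Tg,115.8,degC,3.0,pcsaft
venetoclax,37,2.5,dry,Tg,111.2,degC,1.5,gordon_taylor
venetoclax,37,2.5,solubility,flag,NA,supersaturated_dry,NA,pcsaft
venetoclax,37,2.5,egt,flag,NA,llps_before_egt,NA,pcsaft
venetoclax,37,2.5,binodal-polymer-rich,water,6.1,wtpc,1.0,pcsaft
venetoclax,37,2.5,binodal-polymer-rich,api,2.47,wtpc,1.0,pcsaft
venetoclax,37,2.5,binodal-polymer-rich,polymer,91.4,wtpc,1.0,pcsaft
venetoclax,37,2.5,binodal-polymer-rich,Tg,66.5,degC,3.0,pcsaft
venetoclax,37,2.5,binodal-api-rich,water,0.2,wtpc,1.0,pcsaft
venetoclax,37,2.5,binodal-api-rich,api,99.8,wtpc,1.0,pcsaft
venetoclax,37,2.5,binodal-api-rich,polymer,0.0,wtpc,1.0,pcsaft
venetoclax,37,2.5,binodal-api-rich,Tg,118.3,degC,3.0,pcsaft
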