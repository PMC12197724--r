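population,parameter,unit,value,dist,p1,p2,p3,lower,upper,description
adults,R_ing,mg/d,100,lognormal,100,60,NA,NA,NA,soil ingestion rate
adults,R_inh,m3/d,14.5,point,NA,NA,NA,NA,NA,air inhalation rate
adults,EF,d/yr,350,point,NA,NA,NA,NA,NA,exposure frequency
adults,ED,yr,24,point,NA,NA,NA,NA,NA,exposure duration
adults,BW,kg,64.3,normal,64.3,10.5,NA,40,100,body weight
adults,AT_nc,d,8760,point,NA,NA,NA,NA,NA,averaging time non-carcinogenic (ED x 365)
adults,AT_ca,d,8760,point,NA,NA,NA,NA,NA,averaging time carcinogenic (ED x 365)
adults,SA,cm2,5700,point,NA,NA,NA,NA,NA,exposed skin surface area
adults,AF,mg/cm2/d,0.07,point,NA,NA,NA,NA,NA,soil-to-skin adherence factor
adults,ABS,-,0.001,point,NA,NA,NA,NA,NA,dermal absorption fraction
adults,PEF,m3/kg,1.36e9,point,NA,NA,NA,NA,NA,particle emission factor
children,R_ing,mg/d,200,lognormal,200,120,NA,NA,NA,soil ingestion rate
children,R_inh,m3/d,7.5,point,NA,NA,NA,NA,NA,air inhalation rate
children,EF,d/yr,350,point,NA,NA,NA,NA,NA,exposure frequency
children,ED,yr,6,point,NA,NA,NA,NA,NA,exposure duration
children,BW,kg,19.2,normal,19.2,3.2,NA,10,35,body weight
children,AT_nc,d,2190,point,NA,NA,NA,NA,NA,averaging time non-carcinogenic (ED x 365)
children,AT_ca,d,2190,point,NA,NA,NA,NA,NA,averaging time carcinogenic (ED x 365)
children,SA,cm2,2800,point,NA,NA,NA,NA,NA,exposed skin surface area
children,AF,mg/cm2/d,0.2,point,NA,NA,NA,NA,NA,soil-to-skin adherence factor
children,ABS,-,0.001,point,NA,NA,NA,NA,NA,dermal absorption fraction
children,PEF,m3/kg,1.36e9,point,NA,NA,NA,NA,NA,particle emission factor
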