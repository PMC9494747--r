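category,variable,stage,mean,sd,mean_below_precision,sd_below_precision
SOI,soil type,1,0.01,0.01,FALSE,FALSE
SOI,soil texture,1,0.05,0.04,FALSE,FALSE
SOI,bulk density,1,0.04,0.15,FALSE,FALSE
SOI,SOC stock,1,0.03,0.13,FALSE,FALSE
SOI,SON stock,1,0.02,0.09,FALSE,FALSE
SOI,pH,1,0.02,0.09,FALSE,FALSE
SOI,soil mineral N,1,0.02,0.07,FALSE,FALSE
SOI,"FC, WFPS, and CEC",1,0.04,0.19,FALSE,FALSE
SOI,other soil information,1,0.01,0.06,FALSE,FALSE
CL,air temperature,1,0.03,0.03,FALSE,FALSE
CL,precipitation,1,0.04,0.03,FALSE,FALSE
CL,solar radiation,1,0.03,0.01,FALSE,FALSE
CL,air humidity,1,0.01,0.01,FALSE,FALSE
CL,atm. pressure,1,0.01,0,FALSE,TRUE
CL,other climate factors,1,0.01,0,FALSE,TRUE
MPDE,crop residues,1,0.02,0.01,FALSE,FALSE
MPDE,fertilization rates,1,0.06,0.03,FALSE,FALSE
MPDE,fertilization mode,1,0.02,0.01,FALSE,FALSE
MPDE,fertilizer type,1,0.03,0.02,FALSE,FALSE
MPDE,irrigation,1,0.05,0.02,FALSE,FALSE
MPDE,frequency of plowing,1,0.02,0.01,FALSE,FALSE
MPDE,frequency other activities,1,0.02,0.01,FALSE,FALSE
MPDE,intercropping,1,0.02,0.01,FALSE,FALSE
MPDE,"freq. harvest, grazing, and cut in grass",1,0.03,0.01,FALSE,FALSE
SI,crop type,1,0.02,0.01,FALSE,FALSE
SI,location,1,0.01,0.01,FALSE,FALSE
SI,terrain info,1,0,0,TRUE,TRUE
SI,experimental length,1,0.01,0.02,FALSE,FALSE
SI,mean regional yield,2,0.01,0.01,FALSE,FALSE
LTCL,air temperature,2,0.01,0,FALSE,TRUE
LTCL,precipitation,2,0.01,0.01,FALSE,FALSE
LTCL,solar radiation,2,0.01,0.01,FALSE,FALSE
LTCL,air humidity,2,0,0,TRUE,TRUE
LTCL,atm. pressure,2,0,0,TRUE,TRUE
LTCL,other climate factors,2,0,0,TRUE,TRUE
LTMP,fertilization rates,2,0.01,0.01,FALSE,FALSE
LTMP,fertilization mode,2,0,0,TRUE,TRUE
LTMP,fertilizer type,2,0,0,TRUE,TRUE
LTMP,irrigation,2,0.01,0.01,FALSE,FALSE
LTMP,frequency of harvest,2,0.01,0.01,FALSE,FALSE
LTMP,frequency of plowing,2,0.01,0,FALSE,TRUE
LTMP,frequency other activities,2,0,0,TRUE,TRUE
LTMP,crop residues,2,0.01,0,FALSE,TRUE
LTMP,intercropping,2,0.01,0,FALSE,TRUE
LTMP,land use history,2,0.01,0.01,FALSE,FALSE
EDS,annual extracted yield,3,0.03,0.03,FALSE,FALSE
EDS,"vegetation data (phenology, LAI)",3,0.03,0.03,FALSE,FALSE
EDS,soil temperature,4,0.01,0.01,FALSE,FALSE
EDS,soil moisture,4,0.03,0.01,FALSE,FALSE
EDS,soil mineral N,4,0.02,0.01,FALSE,FALSE
EDS,SOC and SON,5,0.02,0.01,FALSE,FALSE
EDS,GPP and NEP,5,0.02,0.02,FALSE,FALSE
EDS,NEE and Reco,5,0.02,0.02,FALSE,FALSE
EDS,soil N losses,5,0.02,0.01,FALSE,FALSE
EDS,N2O and/or CH4,5,0.03,0.03,FALSE,FALSE
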