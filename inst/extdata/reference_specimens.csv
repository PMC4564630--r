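specimen_number,side,sex,age,category,rct_location,coronal_cm,sagittal_cm,posterior_region_present
1460,right,F,67,A,SP,NA,NA,TRUE
1463,right,F,95,A,SP,NA,NA,TRUE
1429,right,F,64,A,SP,NA,NA,TRUE
1425,right,M,89,A,SP,NA,NA,TRUE
1458,right,F,73,B,SP,1.88,1.63,TRUE
1450,right,F,77,B,SP,1.04,2.08,TRUE
1447,right,F,94,B,SP,1.47,1.52,TRUE
1447,left,F,94,B,SP,1.40,1.17,TRUE
1455,right,F,82,C,"SP, SSC, ISP",3.33,3.84,FALSE
1427,right,M,76,C,"SP, SSC, ISP",5.0,3.00,FALSE
1444,right,M,83,C,"SP, SSC, ISP",2.59,3.76,TRUE
1445,left,F,91,C,"SP, SSC, ISP",2.59,3.67,TRUE
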