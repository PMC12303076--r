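atc_code,drug_class,drug_name,default_dose_mg
L01FC01,daratumumab,daratumumab,1800
L01FC02,isatuximab,isatuximab,500
L01XG01,bortezomib,bortezomib,2
L01XG02,carfilzomib,carfilzomib,56
L01XG03,ixazomib,ixazomib,4
L04AX02,thalidomide,thalidomide,100
L04AX04,lenalidomide,lenalidomide,25
L04AX06,pomalidomide,pomalidomide,4
L04AX09,iberdomide,iberdomide,1.3
H02AB02,corticosteroid,dexamethasone,40
H02AB06,corticosteroid,prednisolone,50
H02AB07,corticosteroid,prednisone,60
L01AA01,cyclophosphamide,cyclophosphamide,500
L01AA03,melphalan,melphalan,16
L01FX08,elotuzumab,elotuzumab,800
L01FX24,teclistamab,teclistamab,108
L01FX27,elranatamab,elranatamab,44
L01FX29,talquetamab,talquetamab,57
L01XL05,car_t,ciltacabtagene autoleucel,1
L01XL07,car_t,idecabtagene vicleucel,1
L01XX99,trial_drug,investigational agent,1
L01BC01,cytarabine,cytarabine,200
L01DB02,anthracycline,daunorubicin,90
L01DB06,anthracycline,idarubicin,12
L01BC07,azacitidine,azacitidine,75
L01XX52,venetoclax,venetoclax,400
L01EX13,gilteritinib,gilteritinib,120
L01EX10,midostaurin,midostaurin,100
L01XX05,hydroxycarbamide,hydroxycarbamide,1000
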