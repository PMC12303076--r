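name,category,drug_classes,maintenance_flag,event
D-VRd,Anti-CD38,daratumumab;bortezomib;lenalidomide;corticosteroid,FALSE,
D-VTd,Anti-CD38,daratumumab;bortezomib;thalidomide;corticosteroid,FALSE,
D-VCd,Anti-CD38,daratumumab;bortezomib;cyclophosphamide;corticosteroid,FALSE,
D-VMP,Anti-CD38,daratumumab;bortezomib;melphalan;corticosteroid,FALSE,
D-Vd,Anti-CD38,daratumumab;bortezomib;corticosteroid,FALSE,
D-Rd,Anti-CD38,daratumumab;lenalidomide;corticosteroid,FALSE,
D-Pd,Anti-CD38,daratumumab;pomalidomide;corticosteroid,FALSE,
D-mono,Anti-CD38,daratumumab,FALSE,
Isa-KRd,Anti-CD38,isatuximab;carfilzomib;lenalidomide;corticosteroid,FALSE,
Isa-Kd,Anti-CD38,isatuximab;carfilzomib;corticosteroid,FALSE,
Isa-Pd,Anti-CD38,isatuximab;pomalidomide;corticosteroid,FALSE,
VRd,PI-IMID,bortezomib;lenalidomide;corticosteroid,FALSE,
VTd,PI-IMID,bortezomib;thalidomide;corticosteroid,FALSE,
VCd,PI-IMID,bortezomib;cyclophosphamide;corticosteroid,FALSE,
Pom-Vd,PI-IMID,pomalidomide;bortezomib;corticosteroid,FALSE,
IRd,PI-IMID,ixazomib;lenalidomide;corticosteroid,FALSE,
Vd,PI,bortezomib;corticosteroid,FALSE,
KRd,PI,carfilzomib;lenalidomide;corticosteroid,FALSE,
Kd,PI,carfilzomib;corticosteroid,FALSE,
PCd,IMID,pomalidomide;cyclophosphamide;corticosteroid,FALSE,
Rd,IMID,lenalidomide;corticosteroid,FALSE,
Pd,IMID,pomalidomide;corticosteroid,FALSE,
P-mono,IMID,pomalidomide,FALSE,
Lenalidomide maintenance,IMID,lenalidomide,TRUE,
Iberdomide maintenance,IMID,iberdomide,TRUE,
Tal-PD,Bispecific,talquetamab;pomalidomide;daratumumab,FALSE,
Tec,Bispecific,teclistamab,FALSE,
Elr,Bispecific,elranatamab;corticosteroid,FALSE,
Trial medication,Bispecific,trial_drug,FALSE,
CAR-T,CAR-T,car_t,FALSE,
EPd,Other,elotuzumab;pomalidomide;corticosteroid,FALSE,
ERd,Other,elotuzumab;lenalidomide;corticosteroid,FALSE,
Melphalan,Other,melphalan,FALSE,
Bridging,Other,cyclophosphamide;corticosteroid,FALSE,
Auto-SCT,HSCT,,FALSE,auto
Allo-SCT,HSCT,,FALSE,allo
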