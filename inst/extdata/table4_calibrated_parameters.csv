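parameter,design_variable,ligament,specimen1_kla,specimen1_rks,specimen2_kla,specimen2_rks
reference_strain,X1,ACL_AM,1.14,1.07,1.16,1.14
reference_strain,X2,ACL_PL,1.00,1.00,1.21,1.23
reference_strain,X3,LCL,0.94,0.96,0.76,1.06
reference_strain,X4,sMCL_A,0.79,0.80,1.05,0.94
reference_strain,X5,sMCL_M,0.90,0.91,1.00,0.92
reference_strain,X6,sMCL_P,0.84,0.85,0.98,0.90
reference_strain,X7,dMCL,0.95,0.94,0.79,0.74
reference_strain,X8,PCL_AL,0.91,0.92,0.88,0.89
reference_strain,X9,PCL_PM,0.93,0.94,0.87,0.94
reference_strain,X10,ALS,1.00,1.00,0.76,0.82
reference_strain,X11,PFL,0.99,1.14,1.15,1.15
reference_strain,X12,POL,1.06,1.00,0.92,0.90
reference_strain,X13,PCAP_M,1.25,1.25,1.08,1.11
reference_strain,X14,PCAP_L,1.17,1.22,1.12,1.14
stiffness,X15,ACL_AM,79.41,68.53,103.85,79.21
stiffness,X16,ACL_PL,114.56,115.94,50.19,58.17
stiffness,X17,LCL,90.35,92.57,111.76,125.14
stiffness,X18,sMCL,95.58,102.06,85.05,40.65
stiffness,X19,dMCL,157.53,153.26,111.79,133.03
stiffness,X20,PCL_AL,72.87,77.64,64.25,63.70
stiffness,X21,PCL_PM,82.13,85.37,30.17,30.14
stiffness,X22,ALS,120.16,114.86,53.58,49.17
stiffness,X23,PFL,19.90,32.56,89.52,65.68
stiffness,X24,POL,73.99,65.06,71.60,66.43
stiffness,X25,PCAP_M,71.12,74.38,72.41,71.49
stiffness,X26,PCAP_L,61.58,60.51,70.00,67.23
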