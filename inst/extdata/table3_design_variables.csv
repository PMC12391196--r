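ligament,group,abbrev,n_fibers,strain_dv,strain_lo,strain_hi,stiffness_dv,stiffness_lo,stiffness_hi
Anteromedial Bundle of ACL,ACL,ACL_AM,2,X1,0.95,1.25,X15,50,150
Posterolateral Bundle of ACL,ACL,ACL_PL,2,X2,0.95,1.25,X16,50,150
Main Bundle of LCL,LCL,LCL,3,X3,0.55,1.15,X17,60,200
Superficial Anterior Fiber of MCL,sMCL,sMCL_A,1,X4,0.70,1.05,X18,40,180
Superficial Middle Fiber of MCL,sMCL,sMCL_M,1,X5,0.70,1.05,X18,40,180
Superficial Posterior Fiber of MCL,sMCL,sMCL_P,1,X6,0.70,1.05,X18,40,180
Deep Bundle Fiber of MCL,dMCL,dMCL,3,X7,0.55,1.05,X19,40,180
Anterolateral Bundle of PCL,PCL,PCL_AL,2,X8,0.85,1.15,X20,30,100
Posteromedial Bundle of PCL,PCL,PCL_PM,2,X9,0.85,1.25,X21,30,100
Anterolateral Structure,ALS,ALS,2,X10,0.75,1.25,X22,20,125
Popliteofibular Ligament,PFL,PFL,3,X11,0.85,1.15,X23,10,90
Posterior Oblique Ligament,POL,POL,2,X12,0.75,1.15,X24,30,95
Medial Posterior Capsule,PCAP,PCAP_M,3,X13,0.85,1.25,X25,50,100
Lateral Posterior Capsule,PCAP,PCAP_L,3,X14,0.85,1.25,X26,50,100
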