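specimen,acl_condition,model,dislocation,ACL,ALS,LCL,MCL_S,MCL_D,POL,PCAP,PCL,PFL
1,intact,KLA,FALSE,46.9,121.8,0.0,0.0,0.0,103.1,0.0,0.0,0.0
1,intact,RKS,FALSE,17.5,145.9,0.0,0.0,0.0,86.2,0.0,0.0,0.0
1,no_acl,KLA,FALSE,0.0,163.7,0.0,0.0,0.9,85.6,0.0,0.0,0.0
1,no_acl,RKS,FALSE,0.0,159.3,0.0,0.0,5.2,81.3,0.0,0.0,0.0
2,intact,KLA,FALSE,175.1,0.3,0.0,215.4,0.0,0.0,0.0,0.0,93.1
2,intact,RKS,FALSE,141.6,28.7,190.2,88.6,0.0,0.0,6.9,95.7,0.4
2,no_acl,KLA,TRUE,0.0,187.3,0.0,148.0,0.0,0.0,29.1,0.0,46.9
2,no_acl,RKS,TRUE,0.0,271.3,41.1,184.5,0.1,0.0,0.6,-0.1,0.1
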