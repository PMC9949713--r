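((Ml_INXA:1,Hc_INXA:1):1,((Bo_INXB:1,Ml_INXB:1):1,(Pb_INXB:1,Hc_INXB:1):1):1,((Bo_INXC:1,Ml_INXC:1):1,(Pb_INXC:1,Hc_INXC:1):1):1,((Bo_INXD:1,Ml_INXD:1):1,(Pb_INXD:1,Hc_INXD:1):1):1,((Pb_INXE.1:1,Hc_INXE.1:1):1,(Pb_INXE.2:1,Hc_INXE.2:1):1):1,(Hc_INXF.1:1,Hc_INXF.2:1):1,((Bo_INXG:1,(Ml_INXG.1:1,Ml_INXG.2:1):1):1,Hc_INXG:1):1,((Bo_INXH:1,Ml_INXH:1):1,Hc_INXH:1):1,(Ml_INXJ:1,(Pb_INXJ:1,(Hc_INXJ.1:1,Hc_INXJ.2:1):1):1):1,(Bo_INXK:1,Hc_INXK:1):1,((Bo_INXL:1,Ml_INXL:1):1,(Pb_INXL:1,Hc_INXL:1):1):1,((Bo_INXM:1,Ml_INXM:1):1,(Pb_INXM:1,Hc_INXM:1):1):1,(Bo_INXN:1,(Pb_INXN:1,Hc_INXN:1):1):1,((Bo_INXO:1,Ml_INXO:1):1,Hc_INXO:1):1,(Bo_INXP:1,Ml_INXP:1):1,(Bo_INXQ:1,Hc_INXQ:1):1,(Bo_INXR:1,Hc_INXR:1):1):0;
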