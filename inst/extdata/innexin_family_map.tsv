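gene	family
Ml_INXA	INXA
Hc_INXA	INXA
Bo_INXB	INXB
Ml_INXB	INXB
Pb_INXB	INXB
Hc_INXB	INXB
Bo_INXC	INXC
Ml_INXC	INXC
Pb_INXC	INXC
Hc_INXC	INXC
Bo_INXD	INXD
Ml_INXD	INXD
Pb_INXD	INXD
Hc_INXD	INXD
Pb_INXE.1	INXE
Hc_INXE.1	INXE
Pb_INXE.2	INXE
Hc_INXE.2	INXE
Hc_INXF.1	INXF
Hc_INXF.2	INXF
Bo_INXG	INXG
Ml_INXG.1	INXG
Ml_INXG.2	INXG
Hc_INXG	INXG
Bo_INXH	INXH
Ml_INXH	INXH
Hc_INXH	INXH
Ml_INXJ	INXJ
Pb_INXJ	INXJ
Hc_INXJ.1	INXJ
Hc_INXJ.2	INXJ
Bo_INXK	INXK
Hc_INXK	INXK
Bo_INXL	INXL
Ml_INXL	INXL
Pb_INXL	INXL
Hc_INXL	INXL
Bo_INXM	INXM
Ml_INXM	INXM
Pb_INXM	INXM
Hc_INXM	INXM
Bo_INXN	INXN
Pb_INXN	INXN
Hc_INXN	INXN
Bo_INXO	INXO
Ml_INXO	INXO
Hc_INXO	INXO
Bo_INXP	INXP
Ml_INXP	INXP
Bo_INXQ	INXQ
Hc_INXQ	INXQ
Bo_INXR	INXR
Hc_INXR	INXR
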