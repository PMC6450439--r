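innate	synthetic membership for illustration	Cd14	Csf3r	Fcgr4	Cd68	Cd84	Slc11a1	Il1a
adaptive	synthetic membership for illustration	Cd3d	Cd3e	Cd3g	Cd6	Sh2d1a	Cd8a	Cd8b1
B-cell functions	synthetic membership for illustration	Ms4a1	Tnfrsf17	Cd19	Cr2
T-cell functions	synthetic membership for illustration	Cd3d	Cd3e	Tbx21	Foxp3	Lag3
chemokines and receptors	synthetic membership for illustration	Cxcl1	Cxcl5	Ccl2	Ccl3	Ccl7	Ccr2
cytokines and receptors	synthetic membership for illustration	Il1a	Il1b	Il6	Tnf	Il10
interferon	synthetic membership for illustration	Irf7	Ifit3	Rsad2	Irf4	Stat1
complement	synthetic membership for illustration	C3ar1	C1qa	C1qb	C2	C3
TNF superfamily	synthetic membership for illustration	Tnf	Tnfsf13b	Tnfrsf17	Cd40
adhesion	synthetic membership for illustration	Icam1	Vcam1	Sell	Itgam
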