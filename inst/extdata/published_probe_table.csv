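# Published differential-expression table (both analyses, top 15 probe sets
# by rank): probe, p-value, Storey-Tibshirani q-value, expected false
# positives (q x rank) and direction of change in BCR vs non-BCR.
analysis,rank,probe,gene,p_value,q_value,expected_fp,direction
tumor_only,1,ERG8,ERG,3.50e-05,0.00287,0.003,down_in_BCR
tumor_only,2,ERG1.ERG2.ERG3,ERG,0.00012,0.00505,0.010,down_in_BCR
tumor_only,3,Pan.ERG,ERG,0.00036,0.00951,0.029,down_in_BCR
tumor_only,4,GGT1,GGT1,0.00046,0.00951,0.038,down_in_BCR
tumor_only,5,HDAC1,HDAC1,0.00158,0.02542,0.127,down_in_BCR
tumor_only,6,KLK2,KLK2,0.00197,0.02542,0.153,down_in_BCR
tumor_only,7,MYO6,MYO6,0.00214,0.02542,0.178,down_in_BCR
tumor_only,8,PLA2G7,PLA2G7,0.00283,0.02941,0.235,down_in_BCR
tumor_only,9,T2.ERG.exon4.fusion,ERG,0.00319,0.02947,0.265,down_in_BCR
tumor_only,10,BICD1,BICD1,0.00509,0.04225,0.422,down_in_BCR
tumor_only,11,CACNA1D,CACNA1D,0.00993,0.07502,0.825,down_in_BCR
tumor_only,12,ACPP,ACPP,0.02298,0.15908,1.909,up_in_BCR
tumor_only,13,FAS,FAS,0.03467,0.22155,2.880,down_in_BCR
tumor_only,14,T2.ERG.exon2.fusion,ERG,0.03828,0.22718,3.180,down_in_BCR
tumor_only,15,C.MYC,C.MYC,0.06511,0.34971,5.246,down_in_BCR
tumor_vs_normal,1,Pan.ERG,ERG,0.00025,0.01594,0.016,down_in_BCR
tumor_vs_normal,2,ERG8,ERG,0.00036,0.01594,0.032,down_in_BCR
tumor_vs_normal,3,ERG1.ERG2.ERG3,ERG,0.00124,0.03686,0.111,down_in_BCR
tumor_vs_normal,4,T2.ERG.exon4.fusion,ERG,0.00342,0.06245,0.250,down_in_BCR
tumor_vs_normal,5,TP53,TP53,0.00349,0.06245,0.312,down_in_BCR
tumor_vs_normal,6,HDAC1,HDAC1,0.00575,0.08562,0.514,down_in_BCR
tumor_vs_normal,7,NCOA2,NCOA2,0.01971,0.24723,1.731,up_in_BCR
tumor_vs_normal,8,VEGFA,VEGFA,0.02213,0.24723,1.978,up_in_BCR
tumor_vs_normal,9,PTEN,PTEN,0.03389,0.30341,2.731,down_in_BCR
tumor_vs_normal,10,ACPP,ACPP,0.03911,0.30341,3.034,up_in_BCR
tumor_vs_normal,11,KLF4,KLF4,0.04010,0.30341,3.337,up_in_BCR
tumor_vs_normal,12,TMPRSS2,TMPRSS2,0.04074,0.30341,3.641,up_in_BCR
tumor_vs_normal,13,FAS,FAS,0.04674,0.32132,4.177,down_in_BCR
tumor_vs_normal,14,HSP27,HSP27,0.06458,0.39413,5.518,up_in_BCR
tumor_vs_normal,15,T2.ERG.exon2.fusion,ERG,0.06616,0.39413,5.912,down_in_BCR
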