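locus,snp_id,allele1,allele2,cut_allele,enzyme,recognition_site,primer_set,pcr_length,digest_fragments
Chr1,rs21953123,C,T,C,HpyCH4II,ACTGT,original,311,228;83
Chr1,rs21953123,C,T,C,HpyCH4II,ACTGT,additional,417,260;157
Chr10,rs22078677,A,C,C,BanI,GGCACC,original,374,19;355
Chr10,rs22078677,A,C,C,BanI,GGCACC,original_fwd_new_rev,161,19;142
Chr15,rs22422063,C,A,C,NciI,CCCGG,original,375,196;179
Chr15,rs22422063,C,A,C,NciI,CCCGG,original_fwd_new_rev,443,227;216
Chr21,rs22923291,G,A,G,Fnu4HI,GCTGC,original,349,310;39
Chr21,rs22923291,G,A,G,Fnu4HI,GCTGC,new_fwd_original_rev,410,384;39
Chr37,rs24025150,G,A,G,HpaII,CCGG,original,374,28;346
Chr37,rs24025150,G,A,G,HpaII,CCGG,original_fwd_new_rev,133,28;105
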