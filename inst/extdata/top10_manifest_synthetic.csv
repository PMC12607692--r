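IlmnID,UCSC_RefGene_Name,CHR,UCSC_RefGene_Group,Relation_to_UCSC_CpG_Island,Regulatory_Feature_Group
cg09760986,ABCG2,4,Body,S_Shore,unclassified
cg22792063,ABHD4,14,TSS200,Island,promoter-associated
cg00807892,MOBKL1A,4,TSS200,Island,promoter-associated
cg25282780,AK3,9,TSS1500,Island,promoter-associated
cg09321097,SDE2,1,1stExon,Island,promoter-associated
cg26811976,PRAMEF4,1,~,~,
cg07891983,CREM,10,~,~,
cg04402799,CDH4,20,~,~,
cg03232960,BRAT1,7,5'UTR,Island,promoter-associated
cg00136968,SDK1,7,~,~,
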