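molecule_id,smiles,target_id,activity_type,measure,value_nM,qualifier,confidence,comment
M01,CCO,T1,antagonist,IC50,10,=,9,
M02,CCCO,T1,antagonist,IC50,50,=,8,
M03,CCCCO,T1,antagonist,IC50,100,=,9,outside typical range
M04,CCN,T1,antagonist,IC50,200,=,9,potential transcription error
M05,CCCN,T1,antagonist,IC50,10,>,9,
M06,CCCCN,T1,antagonist,IC50,10,<,9,
M07,CCOC,T1,antagonist,IC50,10,~,9,
M08,CCCOC,T1,antagonist,IC50,150000,=,9,
M09,CCCCOC,T1,antagonist,IC50,200000,=,9,
M10,CCCC,T1,antagonist,IC50,10,=,7,
M11,CCCCC,T1,antagonist,IC50,10,=,5,
M12,CCCCCC,T1,antagonist,IC50,10,=,9,
M13,CCCCCCC,T1,antagonist,IC50,10,=,9,
M14,Oc1ccccc1,T1,antagonist,IC50,10,=,9,
M14,Oc1ccccc1,T1,antagonist,IC50,50,=,9,
M15,CCOCC,T1,antagonist,IC50,5,=,9,
M15,CCOCC,T1,antagonist,IC50,25,=,9,
M16,O=[N+]([O-])c1ccccc1,T1,antagonist,IC50,10,=,9,
M17,CC(=O)Cl,T1,antagonist,IC50,10,=,9,
M18,CCCCCCCC,T1,antagonist,IC50,10,=,9,
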