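# provenance: UniProt P49768 (PSEN1_HUMAN) membrane topology annotation; 9 transmembrane helices, cytoplasmic N-terminus and large TM6-TM7 cytoplasmic loop; lumenal/extracellular segments labelled "other"
start_codon,end_codon,label,feature
1,82,CY,cytoplasmic N-terminus
83,103,TM,TM helix 1
104,132,other,lumenal loop TM1-TM2
133,153,TM,TM helix 2
154,163,CY,cytoplasmic loop TM2-TM3
164,184,TM,TM helix 3
185,194,other,lumenal loop TM3-TM4
195,215,TM,TM helix 4
216,220,CY,cytoplasmic loop TM4-TM5
221,241,TM,TM helix 5
242,247,other,lumenal loop TM5-TM6
248,268,TM,TM helix 6
269,380,CY,large cytoplasmic loop TM6-TM7
381,401,TM,TM helix 7
402,407,other,lumenal loop TM7-TM8
408,428,TM,TM helix 8
429,432,CY,cytoplasmic loop TM8-TM9
433,453,TM,TM helix 9
454,467,other,lumenal C-terminus
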