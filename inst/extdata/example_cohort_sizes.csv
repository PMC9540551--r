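condition,group,n
appendicitis,es,247506
appendicitis,nes,20638
gallstone_disease,es,52004
gallstone_disease,nes,188973
diverticular_disease,es,15772
diverticular_disease,nes,123097
hernia,es,62559
hernia,nes,43873
intestinal_obstruction,es,40550
intestinal_obstruction,nes,92523
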