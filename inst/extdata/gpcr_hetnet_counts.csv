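quantity,value
protomers,156
heteromer_pairs,260
family_f1_protomers,128
family_f2_protomers,15
family_f3_protomers,13
family_f2_total_putative,46
family_f3_total_putative,22
edges_f1_f1,219
edges_f2_f2,15
edges_f3_f3,17
edges_interfamily,9
disconnected_protomers,23
degree_one_protomers,57
clustered_protomers,56
controversial_pairs,15
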