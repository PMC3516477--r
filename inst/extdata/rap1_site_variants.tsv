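# Rap1 binding-site sequences: the genome-wide consensus and the weak
# silencer variants. The HMR-E variant is printed in three forms in the
# source literature; all three are kept, labelled, with no canonical choice.
name	sequence
rap1_genomewide_consensus	ACACCCATACATT
hmr_e_rap1_variant_a	AAACCCATCAACC
hmr_e_rap1_variant_b	AAAACCCATCAAC
hmr_e_rap1_variant_c	AAACCCATAAC
hml_e_rap1_site	AAAACCCATTCAT
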