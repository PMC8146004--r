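# Example custom assay registry entry. Built-in assays need no file;
# entries here are merged over them (names must not collide).
assays:
  - name: DEMO_rs0000001
    gene: DEMO
    snp_id: rs0000001
    fam_allele: A
    hex_allele: G
    amplicon_length_bp: 80
    metadata:
      note: synthetic demonstration assay, not a real design
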