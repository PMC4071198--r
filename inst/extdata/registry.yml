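# Fixture registry configuration: the two data tables used by the bundled
# recipes. Column order is the on-disk field order of each .loc file.
tables:
  - name: all_fasta
    columns: [value, dbkey, name, path]
    loc_path: all_fasta.loc
    key_column: value
    allow_duplicates: false
  - name: toy_indexes
    columns: [value, dbkey, name, path]
    loc_path: toy_index.loc
    key_column: value
    allow_duplicates: false
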