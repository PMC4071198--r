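# Build a toy index (per-sequence lengths + sha256) for a FASTA file and
# register it in toy_indexes. Stands in for a real aligner index builder.
id: toy_index
version: "1.0.0"
name: Toy sequence indexer
description: >
  Deterministically derives <fasta>.sizes and <fasta>.sum next to a staged
  copy of the input FASTA. algorithm=auto selects small/large from the total
  base count (documented fixture threshold: 50000 bases).
params:
  - name: dbkey
    kind: text
  - name: name
    kind: text
    default: ""
  - name: fasta
    kind: input_path
  - name: algorithm
    kind: choice
    choices: [auto, small, large]
    default: auto
builtin: toy_index
outputs:
  - table: toy_indexes
    move_policy: copy_dir
    translations:
      - column: path
        kind: template
        template: "${data_root}/${table}/${value}/${raw}"
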