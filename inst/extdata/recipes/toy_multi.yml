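# Multi-table demonstration: one run adds entries to two tables at once
# (two into all_fasta, three into toy_indexes). No files are moved.
id: toy_multi
version: "1.0.0"
name: Multi-table demo
description: >
  Emits deterministic entries into both registry tables from one run,
  demonstrating that a single entry bundle may span several data tables.
params:
  - name: prefix
    kind: text
    default: demo
builtin: toy_multi
outputs:
  - table: all_fasta
    move_policy: none
    translations: []
  - table: toy_indexes
    move_policy: none
    translations: []
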