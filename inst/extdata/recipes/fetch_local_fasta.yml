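# Register a local FASTA file as a reference genome in all_fasta.
id: fetch_local_fasta
version: "1.0.0"
name: Fetch local FASTA
description: >
  Stages a local FASTA file and registers it in the all_fasta table. The raw
  entry's path is the FASTA base name; the path translation rewrites it to
  the installed location under the data root.
params:
  - name: dbkey
    kind: text
  - name: name
    kind: text
    default: ""
  - name: fasta
    kind: input_path
builtin: fetch_local_fasta
outputs:
  - table: all_fasta
    move_policy: copy_file
    translations:
      - column: path
        kind: template
        template: "${data_root}/${table}/${value}/${raw}"
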