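{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "refasset entry bundle (entries.json)",
  "description": "Written by the recipe executable into the staging directory; describes the new registry entries. One bundle may add any number of entries to any number of declared tables.",
  "type": "object",
  "required": ["data_tables"],
  "properties": {
    "data_tables": {
      "type": "object",
      "description": "Mapping of data-table name to its new raw entries. Every table must be declared by the recipe's output declarations.",
      "additionalProperties": {
        "type": "array",
        "items": {
          "type": "object",
          "description": "One raw entry: flat column-name to string-value mapping. Values are raw (e.g. a file base name) and may be rewritten by the recipe's value translations before commit.",
          "additionalProperties": {"type": "string"}
        }
      }
    }
  }
}
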