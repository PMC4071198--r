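{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "refasset parameter bundle (params.json)",
  "description": "Written by the engine into the staging directory before invoking a recipe; the file's path is appended as the command's final token.",
  "type": "object",
  "required": ["params", "staging_dir", "settings"],
  "properties": {
    "params": {
      "type": "object",
      "description": "Normalized parameter bindings, keyed by parameter name.",
      "additionalProperties": {"type": ["string", "integer", "boolean"]}
    },
    "staging_dir": {
      "type": "string",
      "description": "Absolute path of the per-run staging directory (empty at creation, unique per run)."
    },
    "settings": {
      "type": "object",
      "required": ["data_root"],
      "properties": {
        "data_root": {
          "type": "string",
          "description": "Absolute path of the permanent managed data store."
        }
      }
    }
  }
}
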