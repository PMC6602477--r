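{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "trnafeat export",
  "description": "Layout of JSON files written by write_export(): a provenance header and a map of named tables, each an array of row objects.",
  "type": "object",
  "required": ["meta", "tables"],
  "properties": {
    "meta": {
      "type": "object",
      "description": "Provenance: tool version, command line, input digests."
    },
    "tables": {
      "type": "object",
      "additionalProperties": {
        "type": "array",
        "items": { "type": "object" }
      }
    }
  }
}
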