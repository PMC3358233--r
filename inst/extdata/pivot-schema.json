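{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "ImmunoCube pivot export",
  "type": "object",
  "required": ["query", "unitsHidden", "cells"],
  "properties": {
    "query": {
      "type": "object",
      "required": ["rows", "cols", "measures"],
      "properties": {
        "rows": {"type": "array", "items": {"type": "string"}},
        "cols": {"type": "array", "items": {"type": "string"}},
        "filters": {"type": "object"},
        "measures": {"type": "array", "items": {"type": "string"}}
      }
    },
    "rowLevels": {"type": "array", "items": {"type": "string"}},
    "colLevels": {"type": "array", "items": {"type": "string"}},
    "unitsHidden": {"type": "boolean"},
    "cells": {
      "type": "object",
      "description": "column-oriented cell table: member columns (strings, '(all)' marks a roll-up member) and one numeric column per measure"
    }
  }
}
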