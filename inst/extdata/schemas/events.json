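{
    "id": "events",
    "kind": "tsv",
    "columns": [
        {"name": "onset", "type": "number", "required": true, "min": 0},
        {"name": "duration", "type": "number_or_na", "required": true,
         "min": 0},
        {"name": "trial_type", "type": "string", "required": false},
        {"name": "value", "type": "string", "required": false},
        {"name": "sample", "type": "integer_or_na", "required": false,
         "min": 0}
    ]
}
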