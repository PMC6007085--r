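{
    "id": "participants",
    "kind": "tsv",
    "columns": [
        {"name": "participant_id", "type": "string", "required": true,
         "unique": true, "pattern": "^sub-[A-Za-z0-9]+$"}
    ]
}
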