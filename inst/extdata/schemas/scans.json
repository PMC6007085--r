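{
    "id": "scans",
    "kind": "tsv",
    "columns": [
        {"name": "filename", "type": "string", "required": true,
         "unique": true},
        {"name": "acq_time", "type": "datetime_or_na", "required": false}
    ]
}
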