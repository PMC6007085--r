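{
    "id": "channels",
    "kind": "tsv",
    "columns": [
        {"name": "name", "type": "string", "required": true, "unique": true},
        {"name": "type", "type": "string", "required": true,
         "vocab": ["MEGMAG", "MEGGRADAXIAL", "MEGGRADPLANAR", "MEGREFMAG",
                   "MEGREFGRADAXIAL", "EEG", "EOG", "ECG", "EMG", "TRIG",
                   "MISC"]},
        {"name": "units", "type": "string", "required": true},
        {"name": "low_cutoff", "type": "number_or_na", "required": false},
        {"name": "high_cutoff", "type": "number_or_na", "required": false},
        {"name": "status", "type": "string", "required": false,
         "vocab": ["good", "bad"]},
        {"name": "status_description", "type": "string", "required": false}
    ]
}
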