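{
    "id": "dataset_description",
    "kind": "json",
    "key_order": [
        "Name", "BIDSVersion", "Authors", "License", "Acknowledgements",
        "HowToAcknowledge", "Funding", "ReferencesAndLinks", "DatasetDOI"
    ],
    "required": {
        "Name": "string",
        "BIDSVersion": "string"
    },
    "optional": {
        "Authors": "string_array",
        "License": "string",
        "Acknowledgements": "string",
        "HowToAcknowledge": "string",
        "Funding": "string_array",
        "ReferencesAndLinks": "string_array",
        "DatasetDOI": "string"
    },
    "vocab": {},
    "exclusive_min": {},
    "min": {}
}
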