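{
    "id": "T1w",
    "kind": "json",
    "key_order": [
        "AnatomicalLandmarkCoordinates", "CoordinateUnits"
    ],
    "required": {
        "AnatomicalLandmarkCoordinates": "landmarks"
    },
    "optional": {
        "CoordinateUnits": "string"
    },
    "vocab": {},
    "exclusive_min": {},
    "min": {}
}
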