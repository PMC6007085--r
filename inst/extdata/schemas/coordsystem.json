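{
    "id": "coordsystem",
    "kind": "json",
    "key_order": [
        "MEGCoordinateSystem", "MEGCoordinateUnits",
        "MEGCoordinateSystemDescription",
        "HeadCoilCoordinates", "HeadCoilCoordinateSystem",
        "HeadCoilCoordinateUnits",
        "AnatomicalLandmarkCoordinates", "AnatomicalLandmarkCoordinateSystem",
        "AnatomicalLandmarkCoordinateUnits",
        "IntendedFor"
    ],
    "required": {
        "MEGCoordinateSystem": "string",
        "MEGCoordinateUnits": "string"
    },
    "optional": {
        "MEGCoordinateSystemDescription": "string",
        "HeadCoilCoordinates": "coilmap",
        "HeadCoilCoordinateSystem": "string",
        "HeadCoilCoordinateUnits": "string",
        "AnatomicalLandmarkCoordinates": "landmarks",
        "AnatomicalLandmarkCoordinateSystem": "string",
        "AnatomicalLandmarkCoordinateUnits": "string",
        "IntendedFor": "string"
    },
    "vocab": {},
    "exclusive_min": {},
    "min": {}
}
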