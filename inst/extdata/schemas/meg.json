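{
    "id": "meg",
    "kind": "json",
    "key_order": [
        "TaskName", "SamplingFrequency", "PowerLineFrequency", "DewarPosition",
        "SoftwareFilters", "DigitizedLandmarks", "DigitizedHeadPoints",
        "Manufacturer", "ManufacturersModelName", "InstitutionName",
        "RecordingDuration", "RecordingType", "EpochLength",
        "MEGChannelCount", "MEGREFChannelCount", "EEGChannelCount",
        "EOGChannelCount", "ECGChannelCount", "EMGChannelCount",
        "MiscChannelCount", "TriggerChannelCount",
        "AssociatedEmptyRoom"
    ],
    "required": {
        "TaskName": "string",
        "SamplingFrequency": "number",
        "PowerLineFrequency": "number",
        "DewarPosition": "string",
        "SoftwareFilters": "object_or_na",
        "DigitizedLandmarks": "boolean",
        "DigitizedHeadPoints": "boolean"
    },
    "optional": {
        "Manufacturer": "string",
        "ManufacturersModelName": "string",
        "InstitutionName": "string",
        "RecordingDuration": "number",
        "RecordingType": "string",
        "EpochLength": "number",
        "MEGChannelCount": "integer",
        "MEGREFChannelCount": "integer",
        "EEGChannelCount": "integer",
        "EOGChannelCount": "integer",
        "ECGChannelCount": "integer",
        "EMGChannelCount": "integer",
        "MiscChannelCount": "integer",
        "TriggerChannelCount": "integer",
        "AssociatedEmptyRoom": "string"
    },
    "vocab": {
        "PowerLineFrequency": [50, 60],
        "RecordingType": ["continuous", "epoched"]
    },
    "exclusive_min": {
        "SamplingFrequency": 0
    },
    "min": {
        "RecordingDuration": 0,
        "MEGChannelCount": 0,
        "MEGREFChannelCount": 0,
        "EEGChannelCount": 0,
        "EOGChannelCount": 0,
        "ECGChannelCount": 0,
        "EMGChannelCount": 0,
        "MiscChannelCount": 0,
        "TriggerChannelCount": 0
    }
}
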