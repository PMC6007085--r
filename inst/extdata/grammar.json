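{
    "entity_order": ["sub", "ses", "task", "acq", "run", "proc"],
    "label_pattern": "^[A-Za-z0-9]+$",
    "run_pattern": "^[0-9]+$",
    "run_pad_width": 2,
    "study_level_names": {
        "participants.tsv": {"suffix": "participants", "extension": "tsv"},
        "participants.json": {"suffix": "participants", "extension": "json"},
        "dataset_description.json": {"suffix": "dataset_description", "extension": "json"}
    },
    "suffixes": {
        "meg": {
            "required": ["sub", "task"],
            "optional": ["ses", "acq", "run", "proc"],
            "extensions": ["json", "fif", "ds", "con", "sqd", "raw", "dat"],
            "directory_extensions": ["ds"],
            "placement": "meg"
        },
        "channels": {
            "required": ["sub", "task"],
            "optional": ["ses", "acq", "run", "proc"],
            "extensions": ["tsv", "json"],
            "directory_extensions": [],
            "placement": "meg"
        },
        "events": {
            "required": ["sub", "task"],
            "optional": ["ses", "acq", "run", "proc"],
            "extensions": ["tsv", "json"],
            "directory_extensions": [],
            "placement": "meg"
        },
        "coordsystem": {
            "required": ["sub"],
            "optional": ["ses", "acq"],
            "extensions": ["json"],
            "directory_extensions": [],
            "placement": "session"
        },
        "headshape": {
            "required": ["sub"],
            "optional": ["ses", "acq"],
            "extensions": null,
            "directory_extensions": [],
            "placement": "session"
        },
        "photo": {
            "required": ["sub"],
            "optional": ["ses", "acq"],
            "extensions": ["jpg"],
            "directory_extensions": [],
            "placement": "session"
        },
        "scans": {
            "required": ["sub"],
            "optional": ["ses"],
            "extensions": ["tsv"],
            "directory_extensions": [],
            "placement": "session"
        },
        "T1w": {
            "required": ["sub"],
            "optional": ["ses", "acq", "run"],
            "extensions": ["json", "nii"],
            "directory_extensions": [],
            "placement": "anat"
        },
        "participants": {
            "required": [],
            "optional": [],
            "extensions": ["tsv", "json"],
            "directory_extensions": [],
            "placement": "root"
        },
        "dataset_description": {
            "required": [],
            "optional": [],
            "extensions": ["json"],
            "directory_extensions": [],
            "placement": "root"
        }
    }
}
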