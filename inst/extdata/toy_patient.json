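{
  "age": 8,
  "gender": "female",
  "observations": [
    {
      "finding_id": "fever",
      "state": "present",
      "onset_age": 7.9
    },
    {
      "finding_id": "rash",
      "state": "present",
      "onset_age": 7.9
    },
    {
      "finding_id": "arthritis_knee",
      "state": "absent"
    }
  ],
  "acuity": "weeks"
}
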