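{
  "protein": "synthetic",
  "comment": "SYNTHETIC fixture: domain map matching the default 6-domain pincer generator (30 residues per domain).",
  "domains": [
    {"name": "N",    "start": 1,   "end": 30},
    {"name": "L1",   "start": 31,  "end": 60},
    {"name": "PAZ",  "start": 61,  "end": 90},
    {"name": "L2",   "start": 91,  "end": 120},
    {"name": "MID",  "start": 121, "end": 150},
    {"name": "PIWI", "start": 151, "end": 180}
  ],
  "selections": [
    {"name": "tetrad", "residues": [155, 160, 165, 170]}
  ]
}
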