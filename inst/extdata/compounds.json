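[
  {"name": "IBU", "role": "API", "mw": 206.28, "rho": 1.11,
   "tg": -44.68, "tm": 75.08, "dhfus": 24.68, "dcp": 70.91,
   "temp_unit": "C", "energy_unit": "kJ/mol"},
  {"name": "KOL VA64", "role": "polymer", "mw": 65000, "rho": 1.22,
   "tg": 109.3, "temp_unit": "C"},
  {"name": "KOL 17PF", "role": "polymer", "mw": 11000, "rho": 1.23,
   "tg": 132, "temp_unit": "C"},
  {"name": "HPMCAS", "role": "polymer", "mw": 18000, "rho": 1.30,
   "tg": 122.5, "temp_unit": "C"},
  {"name": "EPO", "role": "polymer", "mw": 47000, "rho": 1.14,
   "tg": 57.2, "temp_unit": "C"}
]
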