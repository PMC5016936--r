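{
  "version": "1.0",
  "ltr_length": 780,
  "pseudo_5p_anchor": 256,
  "pseudo_3p_anchor": 326,
  "pbs_window": [784, 801],
  "landmarks": {
    "5ltr": [1, 780],
    "leader": [781, 2717],
    "gag": [2718, 4191],
    "pro-pol": [4195, 7692],
    "pro": [4195, 4980],
    "pol_rt": [4981, 6400],
    "pol_in": [6401, 7692],
    "env": [7720, 9348],
    "3ltr": [9407, 10186],
    "nc_zf1": [4021, 4062],
    "nc_zf2": [4093, 4130],
    "gpyf": [7501, 7521],
    "env_island": [8289, 8318]
  },
  "ltr_regions": {
    "u3": [1, 255],
    "r": [256, 326],
    "u5": [327, 780]
  },
  "recurrent_deletions": [
    [2780, 3209],
    [4513, 6184],
    [6797, 7692],
    [7928, 9114]
  ]
}
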