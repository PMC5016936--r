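{
  "reference_length": 538,
  "domains": {
    "furin_rknr": {
      "start": 314,
      "end": 317,
      "motif": "RKNR"
    },
    "su_cwic": {
      "start": 186,
      "end": 189,
      "motif": "CWIC"
    },
    "tm_cx6cc": {
      "start": 340,
      "end": 348,
      "pattern": "C.{6}CC"
    },
    "rbd_sdggg": {
      "start": 105,
      "end": 115,
      "pattern": "SDGGG.{2}D.{2}R"
    },
    "isd": {
      "start": 370,
      "end": 386
    }
  },
  "residue_checks": {
    "fusion_peptide_332": {
      "position": 332,
      "ref": "A"
    },
    "heptad_433": {
      "position": 433,
      "ref": "R"
    }
  },
  "lqmv_window": [480, 538]
}
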