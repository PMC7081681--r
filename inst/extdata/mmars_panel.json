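{
  "name": "Mmars",
  "members": [
    {
      "species": "eastern grey kangaroo",
      "fwd": {
        "name": "macF",
        "seq": "GCATCCATCTTAATTCTCCTCA"
      },
      "rev": {
        "name": "marR",
        "seq": "GGTTYTAGTATGTAGTTTTCAAA"
      },
      "expected_size": 250
    },
    {
      "species": "swamp wallaby",
      "fwd": {
        "name": "walF",
        "seq": "GCCCTACTTTCATTAGCAC"
      },
      "rev": {
        "name": "marR",
        "seq": "GGTTYTAGTATGTAGTTTTCAAA"
      },
      "expected_size": 425
    },
    {
      "species": "common wombat",
      "fwd": {
        "name": "VUCytBF",
        "seq": "AGCATTCATCGACCTACCCA"
      },
      "rev": {
        "name": "VUCytBR",
        "seq": "TGTTTCTTTGTAGAGGTAGGAG"
      },
      "expected_size": 289
    }
  ],
  "protocol": {
    "annealing_c": 59,
    "cycles": 35
  }
}
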