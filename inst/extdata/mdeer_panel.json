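{
  "name": "Mdeer",
  "members": [
    {
      "species": "fallow deer",
      "fwd": {
        "name": "DDCytBF",
        "seq": "AGCAACCTTAACTCGATTCTTC"
      },
      "rev": {
        "name": "DDCytBR",
        "seq": "AGAGAAATAGGAATAGGATGCC"
      },
      "expected_size": 197
    },
    {
      "species": "red deer",
      "fwd": {
        "name": "CECytbF3",
        "seq": "CGCAGACAAAATCCCCTTTCA"
      },
      "rev": {
        "name": "CERUR",
        "seq": "GTTTTCGATTGTGCTGGTGA"
      },
      "expected_size": 482
    },
    {
      "species": "sambar deer",
      "fwd": {
        "name": "RUCytbF4",
        "seq": "CCAGTGCCTATTCTGAATCTTAGC"
      },
      "rev": {
        "name": "CERUR",
        "seq": "GTTTTCGATTGTGCTGGTGA"
      },
      "expected_size": 161
    }
  ],
  "protocol": {
    "touchdown": "65->60C step -1C/cycle x5, then 30 cycles at 60C"
  }
}
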