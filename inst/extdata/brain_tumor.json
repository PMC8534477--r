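{
  "nodes": [
    {
      "name": "BT",
      "states": ["0", "1"],
      "parents": []
    },
    {
      "name": "IS",
      "states": ["0", "1"],
      "parents": []
    },
    {
      "name": "C",
      "states": ["0", "1"],
      "parents": ["BT", "IS"]
    }
  ]
}
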