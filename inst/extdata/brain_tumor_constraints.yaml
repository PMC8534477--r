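constraints:
- type: cross
  node: C
  state: '1'
  lesser:
    BT: '0'
    IS: '0'
  greater:
    BT: '0'
    IS: '1'
- type: cross
  node: C
  state: '1'
  lesser:
    BT: '0'
    IS: '0'
  greater:
    BT: '1'
    IS: '0'
- type: cross
  node: C
  state: '1'
  lesser:
    BT: '0'
    IS: '0'
  greater:
    BT: '1'
    IS: '1'
- type: cross
  node: C
  state: '1'
  lesser:
    BT: '0'
    IS: '1'
  greater:
    BT: '1'
    IS: '1'
- type: cross
  node: C
  state: '1'
  lesser:
    BT: '1'
    IS: '0'
  greater:
    BT: '1'
    IS: '1'
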