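{
  "name": "two_node",
  "notes": "minimal mutual-antagonism motif, mass action",
  "inputs": [],
  "species": [
    {
      "name": "A",
      "conc": 0,
      "role": ""
    },
    {
      "name": "B",
      "conc": 0,
      "role": ""
    }
  ],
  "reactions": [
    {
      "id": "synthA",
      "kind": "synthesis",
      "substrates": {},
      "products": {
        "A": 1
      },
      "modifiers": [],
      "params": {
        "k": "ksynthA"
      }
    },
    {
      "id": "degA",
      "kind": "decay",
      "substrates": {
        "A": 1
      },
      "products": {},
      "modifiers": [],
      "params": {
        "k": "kdegA"
      }
    },
    {
      "id": "synthB",
      "kind": "synthesis",
      "substrates": {},
      "products": {
        "B": 1
      },
      "modifiers": [],
      "params": {
        "k": "ksynthB"
      }
    },
    {
      "id": "degB",
      "kind": "decay",
      "substrates": {
        "B": 1
      },
      "products": {},
      "modifiers": [],
      "params": {
        "k": "kdegB"
      }
    },
    {
      "id": "inhibB_byA",
      "kind": "mass_action",
      "substrates": {
        "B": 1
      },
      "products": {},
      "modifiers": [
        {
          "species": "A",
          "type": "activator"
        }
      ],
      "params": {
        "k": "kiA"
      }
    },
    {
      "id": "inhibA_byB",
      "kind": "mass_action",
      "substrates": {
        "A": 1
      },
      "products": {},
      "modifiers": [
        {
          "species": "B",
          "type": "activator"
        }
      ],
      "params": {
        "k": "kiB"
      }
    }
  ],
  "parameters": {
    "values": {
      "ksynthA": 1,
      "kdegA": 1,
      "ksynthB": 1,
      "kdegB": 1,
      "kiA": 1,
      "kiB": 1
    },
    "provenance": "two-node constants"
  }
}
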