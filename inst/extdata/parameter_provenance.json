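[
  {
    "parameter": "k1",
    "provenance": "search-derived baseline; see package vignette"
  },
  {
    "parameter": "k2",
    "provenance": "search-derived baseline; see package vignette"
  },
  {
    "parameter": "kdeg1",
    "provenance": "search-derived baseline; see package vignette"
  },
  {
    "parameter": "k3",
    "provenance": "search-derived baseline; see package vignette"
  },
  {
    "parameter": "k4",
    "provenance": "search-derived baseline; see package vignette"
  },
  {
    "parameter": "kdeg2",
    "provenance": "search-derived baseline; see package vignette"
  },
  {
    "parameter": "k12",
    "provenance": "search-derived baseline; see package vignette"
  },
  {
    "parameter": "k5",
    "provenance": "search-derived baseline; see package vignette"
  },
  {
    "parameter": "kdeg4",
    "provenance": "search-derived baseline; see package vignette"
  },
  {
    "parameter": "k6",
    "provenance": "search-derived baseline; see package vignette"
  },
  {
    "parameter": "kdeg3",
    "provenance": "search-derived baseline; see package vignette"
  },
  {
    "parameter": "k7",
    "provenance": "search-derived baseline; see package vignette"
  },
  {
    "parameter": "k8",
    "provenance": "search-derived baseline; see package vignette"
  },
  {
    "parameter": "k9",
    "provenance": "search-derived baseline; see package vignette"
  },
  {
    "parameter": "ki1",
    "provenance": "search-derived baseline; see package vignette"
  },
  {
    "parameter": "kdeg5",
    "provenance": "search-derived baseline; see package vignette"
  },
  {
    "parameter": "k10",
    "provenance": "search-derived baseline; see package vignette"
  },
  {
    "parameter": "kdeg6",
    "provenance": "search-derived baseline; see package vignette"
  },
  {
    "parameter": "ki2",
    "provenance": "search-derived baseline; see package vignette"
  },
  {
    "parameter": "k11",
    "provenance": "search-derived baseline; see package vignette"
  },
  {
    "parameter": "kdeg7",
    "provenance": "search-derived baseline; see package vignette"
  },
  {
    "parameter": "k13",
    "provenance": "search-derived baseline; see package vignette"
  },
  {
    "parameter": "k14",
    "provenance": "search-derived baseline; see package vignette"
  },
  {
    "parameter": "kdeg8",
    "provenance": "search-derived baseline; see package vignette"
  },
  {
    "parameter": "k15",
    "provenance": "search-derived baseline; see package vignette"
  },
  {
    "parameter": "kb1",
    "provenance": "search-derived baseline; see package vignette"
  },
  {
    "parameter": "kdeg9",
    "provenance": "search-derived baseline; see package vignette"
  },
  {
    "parameter": "kb2",
    "provenance": "search-derived baseline; see package vignette"
  },
  {
    "parameter": "kdeg10",
    "provenance": "search-derived baseline; see package vignette"
  },
  {
    "parameter": "Vpkg",
    "provenance": "search-derived baseline; see package vignette"
  },
  {
    "parameter": "Kmcgmp",
    "provenance": "search-derived baseline; see package vignette"
  },
  {
    "parameter": "kdeg11",
    "provenance": "search-derived baseline; see package vignette"
  },
  {
    "parameter": "kt1",
    "provenance": "search-derived baseline; see package vignette"
  },
  {
    "parameter": "kt2",
    "provenance": "search-derived baseline; see package vignette"
  },
  {
    "parameter": "kt4",
    "provenance": "search-derived baseline; see package vignette"
  },
  {
    "parameter": "KT",
    "provenance": "search-derived baseline; see package vignette"
  },
  {
    "parameter": "npkg",
    "provenance": "structural Hill coefficient (fixed)"
  }
]
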