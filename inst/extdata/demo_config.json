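{
  "seed": 1,
  "synthetic": {
    "genomeLength": 300000,
    "islandCount": 8,
    "nSitesIsland": 20,
    "nSitesOutside": 40,
    "nSitesGained": 2,
    "dmrCount": 8,
    "fragmentsPerReplicate": 40000,
    "nTranscripts": 200,
    "tadWidth": 50000
  },
  "trap": { "R0": 1e9, "lambda": 1.5 },
  "dmr": { "window": 1000, "step": 100, "delta": 0.10 }
}
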