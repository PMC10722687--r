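{
  "files": [
    {
      "file": "cause_shares.csv",
      "md5": "64475a9181d35e309e880d5257bf664c"
    },
    {
      "file": "cost_catalogue.csv",
      "md5": "8e139c9cb5f1974c3837aaa3bc4555ea"
    },
    {
      "file": "country.yml",
      "md5": "bca740458c9341f9e94006a203c3a881"
    },
    {
      "file": "interventions.csv",
      "md5": "f109490d3276025c09564eb6936bfcab"
    },
    {
      "file": "rollout.csv",
      "md5": "31a0c6237417c4183dd34c366252ff9a"
    },
    {
      "file": "schedule.csv",
      "md5": "4ea98d25536bdf62686465024aa158be"
    },
    {
      "file": "staffing.csv",
      "md5": "8d966658c8060d0b0c4b712bef4b6c72"
    }
  ]
}
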