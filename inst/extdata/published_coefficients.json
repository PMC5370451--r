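[
  {
    "template": "NTRISS_like", "center": "HCFMUSP", "mechanism": "blunt",
    "b": ["-0.69833769", "0.51106398", "0.79908416", "-0.09919555", "-1.58444558"]
  },
  {
    "template": "NTRISS_like", "center": "UCSDMC", "mechanism": "blunt",
    "b": ["-0.23530206", "0.62672859", "0.98770635", "-0.07369974", "-1.98269784"]
  },
  {
    "template": "NTRISS_like", "center": "HCFMUSP", "mechanism": "penetrating",
    "b": ["-1.85975686", "0.65231593", "0.86044643", "-0.07452259", "-0.31343883"]
  },
  {
    "template": "NTRISS_like", "center": "UCSDMC", "mechanism": "penetrating",
    "b": ["1.8503094", "0.3724069", "1.0745871", "-0.1152176", "-2.9135328"]
  },
  {
    "template": "TRISS_SpO2", "center": "HCFMUSP", "mechanism": "blunt",
    "b": ["-0.68105065", "0.59504995", "0.51134929", "0.29276785", "-0.08129884", "-1.72272683"]
  },
  {
    "template": "TRISS_SpO2", "center": "UCSDMC", "mechanism": "blunt",
    "b": ["0.07350818", "0.96410432", "0.80528143", "0.10331305", "-0.10089655", "-2.12257955"]
  },
  {
    "template": "TRISS_SpO2", "center": "HCFMUSP", "mechanism": "penetrating",
    "b": ["0.4526497", "0.8334234", "0.3053943", "1.1843363", "-0.2724244", "-4.4829665"]
  },
  {
    "template": "TRISS_SpO2", "center": "UCSDMC", "mechanism": "penetrating",
    "b": ["-13.4424770", "1.1728932", "1.3872589", "2.6946416", "-0.1016297", "-3.0394087"]
  },
  {
    "template": "NTRISS_like_SpO2", "center": "HCFMUSP", "mechanism": "blunt",
    "b": ["-0.93885693", "0.47015472", "0.52813273", "0.39359433", "-0.09505282", "-1.70681763"]
  },
  {
    "template": "NTRISS_like_SpO2", "center": "UCSDMC", "mechanism": "blunt",
    "b": ["-1.61070692", "0.65710014", "0.88971953", "0.41984723", "-0.07388783", "-1.99504004"]
  },
  {
    "template": "NTRISS_like_SpO2", "center": "HCFMUSP", "mechanism": "penetrating",
    "b": ["-1.2399835", "0.3143480", "0.7462718", "1.1698218", "-0.1278085", "10.7638537"]
  },
  {
    "template": "NTRISS_like_SpO2", "center": "UCSDMC", "mechanism": "penetrating",
    "b": ["-9.4481884", "0.2461155", "1.6433308", "2.6394271", "-0.1193648", "-3.8592826"]
  }
]
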