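{
  "total_spend": 2256678,
  "benchmark_cost_per_patient": 122.866976681104,
  "total_saving": 322373.49686457,
  "saving_fraction": 0.142853121652522,
  "percentile_method": "linear interpolation (type 7)"
}
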