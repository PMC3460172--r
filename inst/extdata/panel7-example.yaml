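# Example seven-antigen panel definition with synthetic illustrative RU
# cutoffs (not the commercial assay's proprietary cutoffs).
name: panel7_example
dose_response_required: yes
cutoffs:
  p53: 12.0
  NY-ESO-1: 10.5
  CAGE: 16.0
  GBU4-5: 46.0
  MAGEA4: 93.0
  SOX2-B: 9.1
  HuD: 21.5
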