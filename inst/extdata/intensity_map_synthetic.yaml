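# Illustrative work-intensity parameters per sector (NOT study estimates).
# prodMean/prodSD: cumulative-normal loss curve, deg C-WBGT.
# alpha1/alpha2: logistic (Hothaps) workability curve.
services:
  level: 200
  setting: indoor
  prodMean: 34.5
  prodSD: 4
  alpha1: 35
  alpha2: 10.5
industry:
  level: 300
  setting: indoor
  prodMean: 32.5
  prodSD: 4
  alpha1: 33.5
  alpha2: 7
construction:
  level: 400
  setting: outdoor
  prodMean: 30.5
  prodSD: 4
  alpha1: 32
  alpha2: 4
agriculture:
  level: 400
  setting: outdoor
  prodMean: 30.5
  prodSD: 4
  alpha1: 32
  alpha2: 4
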