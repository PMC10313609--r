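human:
  layer_means_um:
    cornified: 15.0
    granular: 5.0
    spinous: 20.0
    basal: 11.64
  epidermis_mean_um: 51.64
  cv: 0.2
  undulation_amplitude_um: 8.0
  undulation_period_um: 100.0
  mki67_positive_fraction: 0.0145
  marker_expression:
    FLG: yes
    CLDN1: yes
    CDH1: yes
keraskin:
  layer_means_um:
    cornified: 30.0
    granular: 22.0
    spinous: 26.0
    basal: 12.33
  epidermis_mean_um: 90.33
  cv: 0.2
  undulation_amplitude_um: 0.0
  undulation_period_um: 100.0
  mki67_positive_fraction: 0.0847
  marker_expression:
    FLG: yes
    CLDN1: yes
    CDH1: yes
pig:
  layer_means_um:
    cornified: 16.3
    granular: 16.5
    spinous: 25.7
    basal: 16.97
  epidermis_mean_um: 75.47
  cv: 0.2
  undulation_amplitude_um: 12.0
  undulation_period_um: 100.0
  mki67_positive_fraction: 0.0173
  marker_expression:
    FLG: no
    CLDN1: yes
    CDH1: yes
rabbit:
  layer_means_um:
    cornified: 2.8933333
    granular: 4.5
    spinous: 4.0
    basal: 5.82
  epidermis_mean_um: 17.2133333
  cv: 0.2
  undulation_amplitude_um: 0.0
  undulation_period_um: 100.0
  mki67_positive_fraction: 0.0275
  marker_expression:
    FLG: no
    CLDN1: no
    CDH1: no
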