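natural_history:
  exit:
    no_cancer:
    - 0.838
    - 80.427
    - 8.448
    localized_Glt7:
    - 0.449
    - 2.041
    - 8.431
    localized_Geq7:
    - 0.811
    - 1.292
    - 4.349
    localized_Ggt7:
    - 0.987
    - 2.94
    - 7.069
    regional_Glt7:
    - 0.45
    - 6.05
    - 4.129
    regional_Geq7:
    - 0.56
    - 4.113
    - 5.546
    regional_Ggt7:
    - 0.823
    - 2.024
    - 2.791
    distant_Glt7:
    - 0.999
    - 0.254
    - 5.373
    distant_Geq7:
    - 0.945
    - 0.806
    - 4.564
    distant_Ggt7:
    - 0.999
    - 1.135
    - 5.521
  stage_split:
  - 0.158
  - 0.388
  - 0.005
  - 0.144
  fr: 1.0
  fr_on_onset: yes
  fr_on_progression: yes
  cycle_method: pointwise
detection:
  clinical_detect:
  - 0.006
  - 0.11
  - 0.604
  - 0.067
  - 0.108
  - 0.407
  - 0.233
  - 0.897
  - 1.0
  screen_sens:
  - 0.55
  - 0.37
  - 0.677
  - 0.456
  psa_specificity: 0.85
  biopsy_sensitivity: 0.9
  biopsy_specificity: 1.0
  participation: 1.0
treatment:
  cure_by_grade:
  - 0.51
  - 0.3
  - 0.11
  cure_distant: 0.0
  rp_periop_mortality: 0.0015
  ae_risk:
    RP:
    - 0.28
    - 0.22
    - 0.0
    RT:
    - 0.15
    - 0.031
    - 0.028
  ae_duration: 5.0
  cure_multiplier: 1.0
utilities:
  baseline:
    age:
    - 0
    - 1
    - 2
    - 3
    - 4
    - 5
    - 6
    - 7
    - 8
    - 9
    - 10
    - 11
    - 12
    - 13
    - 14
    - 15
    - 16
    - 17
    - 18
    - 19
    - 20
    - 21
    - 22
    - 23
    - 24
    - 25
    - 26
    - 27
    - 28
    - 29
    - 30
    - 31
    - 32
    - 33
    - 34
    - 35
    - 36
    - 37
    - 38
    - 39
    - 40
    - 41
    - 42
    - 43
    - 44
    - 45
    - 46
    - 47
    - 48
    - 49
    - 50
    - 51
    - 52
    - 53
    - 54
    - 55
    - 56
    - 57
    - 58
    - 59
    - 60
    - 61
    - 62
    - 63
    - 64
    - 65
    - 66
    - 67
    - 68
    - 69
    - 70
    - 71
    - 72
    - 73
    - 74
    - 75
    - 76
    - 77
    - 78
    - 79
    - 80
    - 81
    - 82
    - 83
    - 84
    - 85
    - 86
    - 87
    - 88
    - 89
    - 90
    - 91
    - 92
    - 93
    - 94
    - 95
    - 96
    - 97
    - 98
    - 99
    - 100
    - 101
    - 102
    - 103
    - 104
    - 105
    - 106
    - 107
    - 108
    - 109
    - 110
    - 111
    - 112
    - 113
    - 114
    - 115
    - 116
    - 117
    - 118
    - 119
    - 120
    utility:
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 1.0
    - 0.996
    - 0.992
    - 0.988
    - 0.984
    - 0.98
    - 0.976
    - 0.972
    - 0.968
    - 0.964
    - 0.96
    - 0.956
    - 0.952
    - 0.948
    - 0.944
    - 0.94
    - 0.936
    - 0.932
    - 0.928
    - 0.924
    - 0.92
    - 0.916
    - 0.912
    - 0.908
    - 0.904
    - 0.9
    - 0.896
    - 0.892
    - 0.888
    - 0.884
    - 0.88
    - 0.876
    - 0.872
    - 0.868
    - 0.864
    - 0.86
    - 0.856
    - 0.852
    - 0.848
    - 0.844
    - 0.84
    - 0.836
    - 0.832
    - 0.828
    - 0.824
    - 0.82
    - 0.816
    - 0.812
    - 0.808
    - 0.804
    - 0.8
    - 0.796
    - 0.792
    - 0.788
    - 0.784
    - 0.78
    - 0.78
    - 0.78
    - 0.78
    - 0.78
    - 0.78
    - 0.78
    - 0.78
    - 0.78
    - 0.78
    - 0.78
    - 0.78
    - 0.78
    - 0.78
    - 0.78
    - 0.78
    - 0.78
    - 0.78
    - 0.78
    - 0.78
    - 0.78
    - 0.78
    - 0.78
    - 0.78
    - 0.78
    - 0.78
    - 0.78
    - 0.78
    - 0.78
    - 0.78
    - 0.78
  distant_clinical: 0.6
  ae_utility:
    RP:
    - 0.89
    - 0.9
    - 0.93
    RT:
    - 0.95
    - 0.93
    - 0.93
  one_time:
  - 0.994
  - 0.753
  - 0.772
  - 0.7
  disutility_multiplier: 1.0
surveillance:
  enabled: no
  interval: 2.0
  max_age: 74.0
max_age: 120.0
days_per_year: 365.25
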