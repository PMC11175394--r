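n_entities: 5000
seed: 1
hiv_records_extra_mean: 2.0
corruption:
  typo_rate: 0.05
  typo_ops:
    substitution: 0.4
    transposition: 0.3
    deletion: 0.15
    insertion: 0.15
  nickname_swap_rate: 0.02
  dob_error_rate: 0.02
  dob_missing_rate: 0.02
  identifier_missing_rate: 0.1
province_weights:
  EC: 0.079839737193559
  FS: 0.079409913574751
  GAU: 0.31166817616628
  KZN: 0.134565494373916
  LIM: 0.075802465345471
  MPU: 0.123451483659027
  NW: 0.070153354926853
  NC: 0.024791612299096
  WC: 0.100317762461047
mobility:
  EC:
    EC: 0.807921553547395
    FS: 0.003653143626226
    GAU: 0.049990386464142
    KZN: 0.009805806575659
    LIM: 0.000576812151509
    MPU: 0.003268602191886
    NW: 0.004422226494905
    NC: 0.003460872909056
    WC: 0.116900596039223
  FS:
    EC: 0.003286294219988
    FS: 0.8215735549971
    GAU: 0.111927314904311
    KZN: 0.003092982795283
    LIM: 0.003286294219988
    MPU: 0.007539145563503
    NW: 0.01005219408467
    NC: 0.007152522714092
    WC: 0.032089696501063
  GAU:
    EC: 0.004531350046791
    FS: 0.019307491503719
    GAU: 0.87090577747131
    KZN: 0.019258237698862
    LIM: 0.015859725163769
    MPU: 0.046594099394178
    NW: 0.011131359897552
    NC: 0.002117913608826
    WC: 0.010294045214993
  KZN:
    EC: 0.010723248916267
    FS: 0.011521788729181
    GAU: 0.468172484599589
    KZN: 0.434177503992699
    LIM: 0.002966005019393
    MPU: 0.06114533424595
    NW: 0.003194159251654
    NC: 0.000798539812914
    WC: 0.007300935432352
  LIM:
    EC: 0.001620089104901
    FS: 0.009113001215067
    GAU: 0.172742000810045
    KZN: 0.002835155933576
    LIM: 0.780882948562171
    MPU: 0.025313892264075
    NW: 0.004455245038477
    NC: 0.000202511138113
    WC: 0.002835155933576
  MPU:
    EC: 0.001865207659786
    FS: 0.013678189505098
    GAU: 0.353145983586173
    KZN: 0.022755533449391
    LIM: 0.021636408853519
    MPU: 0.576224819696593
    NW: 0.004352151206168
    NC: 0.000994777418553
    WC: 0.00534692862472
  NW:
    EC: 0.0054704595186
    FS: 0.027789934354486
    GAU: 0.247483588621444
    KZN: 0.002407002188184
    LIM: 0.013129102844639
    MPU: 0.006783369803063
    NW: 0.664551422319475
    NC: 0.011159737417943
    WC: 0.021225382932166
  NC:
    EC: 0.015479876160991
    FS: 0.0328173374613
    GAU: 0.052631578947368
    KZN: 0.00061919504644
    LIM: 0.001857585139319
    MPU: 0.004953560371517
    NW: 0.011764705882353
    NC: 0.774613003095975
    WC: 0.105263157894737
  WC:
    EC: 0.019280795715379
    FS: 0.00168324407039
    GAU: 0.019280795715379
    KZN: 0.002601377199694
    LIM: 0.000612088752869
    MPU: 0.001224177505738
    NW: 0.001224177505738
    NC: 0.005355776587605
    WC: 0.948737566947207
away_record_rate: 0.05
female_fraction: 0.709
race_weights:
  Black: 0.8964
  Coloured: 0.0501
  White: 0.0475
  Asian: 0.006
age_meanlog: 3.688879454113936
age_sdlog: 0.28
cancer_fraction: 0.15
second_report_rate: 0.1
cancer_type_weights:
  cervix: 0.28
  breast: 0.1
  other: 0.14
  BCC: 0.016666666666667
  bladder: 0.016666666666667
  bone: 0.016666666666667
  Burkitt lymphoma: 0.016666666666667
  Hodgkin lymphoma: 0.016666666666667
  Kaposi sarcoma: 0.16
  kidney: 0.016666666666667
  melanoma: 0.016666666666667
  mesothelioma: 0.016666666666667
  non-Hodgkin lymphoma: 0.07
  pancreas: 0.016666666666667
  prostate: 0.016666666666667
  skin other: 0.016666666666667
  stomach: 0.016666666666667
  testis: 0.016666666666667
  thyroid: 0.016666666666667
  tongue: 0.016666666666667
hiv_result_label_weights:
  positive: 0.7
  negative: 0.2
  unknown: 0.1
missing_diagnosis_province_rate: 0.02
facilities_per_province: 25
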