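si_nominal_max: 47
class_bins:
- label: very_mild
  lo: 1.0
  hi: 10.0
- label: mild
  lo: 11.0
  hi: 20.0
- label: moderate
  lo: 21.0
  hi: 29.0
- label: severe
  lo: 30.0
  hi: 39.0
- label: very_severe
  lo: 40.0
  hi: 47.0
items:
  AAO:
    item_id: AAO
    kind: numeric
    min_grade: 1
    max_grade: 6
    digits: 0
    direction: lower_worse
    missing_policy: refuse
    bins:
    - sex: .na.character
      grade: 1
      lo: 50.0
      hi: Inf
    - sex: .na.character
      grade: 2
      lo: 40.0
      hi: 49.0
    - sex: .na.character
      grade: 3
      lo: 30.0
      hi: 39.0
    - sex: .na.character
      grade: 4
      lo: 15.0
      hi: 29.0
    - sex: .na.character
      grade: 5
      lo: 10.0
      hi: 14.0
    - sex: .na.character
      grade: 6
      lo: 1.0
      hi: 9.0
  MMT:
    item_id: MMT
    kind: numeric
    min_grade: 0
    max_grade: 4
    digits: 0
    direction: lower_worse
    missing_policy: refuse
    bins:
    - sex: .na.character
      grade: 0
      lo: 100.0
      hi: Inf
    - sex: .na.character
      grade: 1
      lo: 90.0
      hi: 99.0
    - sex: .na.character
      grade: 2
      lo: 80.0
      hi: 89.0
    - sex: .na.character
      grade: 3
      lo: 70.0
      hi: 79.0
    - sex: .na.character
      grade: 4
      lo: 0.0
      hi: 69.0
  SIXMWT:
    item_id: SIXMWT
    kind: numeric
    min_grade: 0
    max_grade: 6
    digits: 0
    direction: lower_worse
    missing_policy: refuse
    bins:
    - sex: F
      grade: 0
      lo: 423.0
      hi: Inf
    - sex: F
      grade: 1
      lo: 362.0
      hi: 422.0
    - sex: F
      grade: 2
      lo: 301.0
      hi: 361.0
    - sex: F
      grade: 3
      lo: 240.0
      hi: 300.0
    - sex: F
      grade: 4
      lo: 179.0
      hi: 239.0
    - sex: F
      grade: 5
      lo: 118.0
      hi: 178.0
    - sex: F
      grade: 6
      lo: 0.0
      hi: 117.0
    - sex: M
      grade: 0
      lo: 536.0
      hi: Inf
    - sex: M
      grade: 1
      lo: 476.0
      hi: 535.0
    - sex: M
      grade: 2
      lo: 395.0
      hi: 475.0
    - sex: M
      grade: 3
      lo: 315.0
      hi: 394.0
    - sex: M
      grade: 4
      lo: 234.0
      hi: 314.0
    - sex: M
      grade: 5
      lo: 150.0
      hi: 233.0
    - sex: M
      grade: 6
      lo: 0.0
      hi: 149.0
  GSCG:
    item_id: GSCG
    kind: numeric
    min_grade: 0
    max_grade: 4
    digits: 0
    direction: higher_worse
    missing_policy: refuse
    bins:
    - sex: .na.character
      grade: 0
      lo: 4.0
      hi: 4.0
    - sex: .na.character
      grade: 1
      lo: 5.0
      hi: 8.0
    - sex: .na.character
      grade: 2
      lo: 9.0
      hi: 15.0
    - sex: .na.character
      grade: 3
      lo: 16.0
      hi: 21.0
    - sex: .na.character
      grade: 4
      lo: 22.0
      hi: 27.0
  FVC:
    item_id: FVC
    kind: numeric
    min_grade: 0
    max_grade: 4
    digits: 0
    direction: lower_worse
    missing_policy: worst_if_not_performed
    bins:
    - sex: .na.character
      grade: 0
      lo: 80.0
      hi: Inf
    - sex: .na.character
      grade: 1
      lo: 70.0
      hi: 79.0
    - sex: .na.character
      grade: 2
      lo: 60.0
      hi: 69.0
    - sex: .na.character
      grade: 3
      lo: 50.0
      hi: 59.0
    - sex: .na.character
      grade: 4
      lo: 0.0
      hi: 49.0
  DFVC:
    item_id: DFVC
    kind: numeric
    min_grade: 0
    max_grade: 4
    digits: 0
    direction: higher_worse
    missing_policy: worst_if_not_performed
    bins:
    - sex: .na.character
      grade: 0
      lo: -Inf
      hi: 9.0
    - sex: .na.character
      grade: 1
      lo: 10.0
      hi: 15.0
    - sex: .na.character
      grade: 2
      lo: 16.0
      hi: 20.0
    - sex: .na.character
      grade: 3
      lo: 21.0
      hi: 30.0
    - sex: .na.character
      grade: 4
      lo: 31.0
      hi: Inf
  BMI:
    item_id: BMI
    kind: numeric
    min_grade: 0
    max_grade: 4
    digits: 1
    direction: higher_worse
    missing_policy: refuse
    bins:
    - sex: .na.character
      grade: 0
      lo: -Inf
      hi: 24.9
    - sex: .na.character
      grade: 1
      lo: 25.0
      hi: 29.9
    - sex: .na.character
      grade: 2
      lo: 30.0
      hi: 35.9
    - sex: .na.character
      grade: 3
      lo: 36.0
      hi: 40.0
    - sex: .na.character
      grade: 4
      lo: 40.1
      hi: Inf
  VDD:
    item_id: VDD
    kind: numeric
    min_grade: 0
    max_grade: 2
    digits: 1
    direction: lower_worse
    missing_policy: refuse
    bins:
    - sex: .na.character
      grade: 0
      lo: 30.0
      hi: Inf
    - sex: .na.character
      grade: 1
      lo: 20.0
      hi: 29.9
    - sex: .na.character
      grade: 2
      lo: -Inf
      hi: 19.9
  BMD:
    item_id: BMD
    kind: composite
    min_grade: 0
    max_grade: 2
    digits: 0
    direction: .na.character
    missing_policy: refuse
  BF:
    item_id: BF
    kind: boolean
    min_grade: 0
    max_grade: 1
    digits: 0
    direction: .na.character
    missing_policy: refuse
  BAD:
    item_id: BAD
    kind: boolean
    min_grade: 0
    max_grade: 1
    digits: 0
    direction: .na.character
    missing_policy: refuse
  MVP:
    item_id: MVP
    kind: boolean
    min_grade: 0
    max_grade: 1
    digits: 0
    direction: .na.character
    missing_policy: refuse
  IGG:
    item_id: IGG
    kind: presence
    min_grade: 0
    max_grade: 1
    digits: 0
    direction: .na.character
    missing_policy: refuse
  ERTAE:
    item_id: ERTAE
    kind: boolean
    min_grade: 0
    max_grade: 1
    digits: 0
    direction: .na.character
    missing_policy: refuse

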