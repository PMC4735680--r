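bead_types:
- name: NC
  mass: 87.2
  charge: 1.0
  role: lipid-head
- name: PH
  mass: 94.0
  charge: -1.0
  role: lipid-phosphate
- name: GL
  mass: 41.1
  charge: 0.0
  role: lipid-glycerol
- name: CT
  mass: 42.1
  charge: 0.0
  role: lipid-tail
- name: W
  mass: 54.0
  charge: 0.0
  role: water
- name: RG
  mass: 81.1
  charge: 1.0
  role: cation-ring
- name: CA
  mass: 42.1
  charge: 0.0
  role: cation-tail
- name: CL
  mass: 35.5
  charge: -1.0
  role: anion
- name: NA
  mass: 23.0
  charge: 1.0
  role: sodium
pairs:
- a: NC
  b: NC
  epsilon: 1.5
  sigma: 0.59
  form: 9-6
- a: NC
  b: PH
  epsilon: 1.5
  sigma: 0.57
  form: 9-6
- a: NC
  b: GL
  epsilon: 1.4491377
  sigma: 0.545
  form: 9-6
- a: NC
  b: CT
  epsilon: 1.6431677
  sigma: 0.52
  form: 9-6
- a: NC
  b: W
  epsilon: 1.396424
  sigma: 0.53
  form: 12-4
- a: NC
  b: RG
  epsilon: 1.5491933
  sigma: 0.545
  form: 9-6
- a: NC
  b: CA
  epsilon: 1.6431677
  sigma: 0.52
  form: 9-6
- a: NC
  b: CL
  epsilon: 1.4491377
  sigma: 0.515
  form: 9-6
- a: NC
  b: NA
  epsilon: 1.4491377
  sigma: 0.47
  form: 9-6
- a: PH
  b: PH
  epsilon: 1.5
  sigma: 0.55
  form: 9-6
- a: PH
  b: GL
  epsilon: 1.4491377
  sigma: 0.525
  form: 9-6
- a: PH
  b: CT
  epsilon: 1.6431677
  sigma: 0.5
  form: 9-6
- a: PH
  b: W
  epsilon: 1.396424
  sigma: 0.51
  form: 12-4
- a: PH
  b: RG
  epsilon: 1.5491933
  sigma: 0.525
  form: 9-6
- a: PH
  b: CA
  epsilon: 1.6431677
  sigma: 0.5
  form: 9-6
- a: PH
  b: CL
  epsilon: 1.4491377
  sigma: 0.495
  form: 9-6
- a: PH
  b: NA
  epsilon: 1.4491377
  sigma: 0.45
  form: 9-6
- a: GL
  b: GL
  epsilon: 1.4
  sigma: 0.5
  form: 9-6
- a: GL
  b: CT
  epsilon: 1.5874508
  sigma: 0.475
  form: 9-6
- a: GL
  b: W
  epsilon: 1.3490738
  sigma: 0.485
  form: 12-4
- a: GL
  b: RG
  epsilon: 1.496663
  sigma: 0.5
  form: 9-6
- a: GL
  b: CA
  epsilon: 1.5874508
  sigma: 0.475
  form: 9-6
- a: GL
  b: CL
  epsilon: 1.4
  sigma: 0.47
  form: 9-6
- a: GL
  b: NA
  epsilon: 1.4
  sigma: 0.425
  form: 9-6
- a: CT
  b: CT
  epsilon: 1.8
  sigma: 0.45
  form: 9-6
- a: CT
  b: W
  epsilon: 1.5297059
  sigma: 0.46
  form: 12-4
- a: CT
  b: RG
  epsilon: 1.6970563
  sigma: 0.475
  form: 9-6
- a: CT
  b: CA
  epsilon: 1.8
  sigma: 0.45
  form: 9-6
- a: CT
  b: CL
  epsilon: 1.5874508
  sigma: 0.445
  form: 9-6
- a: CT
  b: NA
  epsilon: 1.5874508
  sigma: 0.4
  form: 9-6
- a: W
  b: W
  epsilon: 1.3
  sigma: 0.47
  form: 12-4
- a: W
  b: RG
  epsilon: 1.4422205
  sigma: 0.485
  form: 12-4
- a: W
  b: CA
  epsilon: 1.5297059
  sigma: 0.46
  form: 12-4
- a: W
  b: CL
  epsilon: 1.3490738
  sigma: 0.455
  form: 12-4
- a: W
  b: NA
  epsilon: 1.3490738
  sigma: 0.41
  form: 12-4
- a: RG
  b: RG
  epsilon: 1.6
  sigma: 0.5
  form: 9-6
- a: RG
  b: CA
  epsilon: 1.6970563
  sigma: 0.475
  form: 9-6
- a: RG
  b: CL
  epsilon: 1.496663
  sigma: 0.47
  form: 9-6
- a: RG
  b: NA
  epsilon: 1.496663
  sigma: 0.425
  form: 9-6
- a: CA
  b: CA
  epsilon: 1.8
  sigma: 0.45
  form: 9-6
- a: CA
  b: CL
  epsilon: 1.5874508
  sigma: 0.445
  form: 9-6
- a: CA
  b: NA
  epsilon: 1.5874508
  sigma: 0.4
  form: 9-6
- a: CL
  b: CL
  epsilon: 1.4
  sigma: 0.44
  form: 9-6
- a: CL
  b: NA
  epsilon: 1.4
  sigma: 0.395
  form: 9-6
- a: NA
  b: NA
  epsilon: 1.4
  sigma: 0.35
  form: 9-6
bonds:
- species: POPC
  beads:
  - 1
  - 2
  eq: 0.47
  k: 1250.0
- species: POPC
  beads:
  - 2
  - 3
  eq: 0.47
  k: 1250.0
- species: POPC
  beads:
  - 3
  - 4
  eq: 0.47
  k: 1250.0
- species: POPC
  beads:
  - 4
  - 5
  eq: 0.45
  k: 1250.0
- species: POPC
  beads:
  - 5
  - 6
  eq: 0.45
  k: 1250.0
- species: POPC
  beads:
  - 6
  - 7
  eq: 0.45
  k: 1250.0
- species: POPC
  beads:
  - 7
  - 8
  eq: 0.45
  k: 1250.0
- species: POPC
  beads:
  - 3
  - 9
  eq: 0.47
  k: 1250.0
- species: POPC
  beads:
  - 9
  - 10
  eq: 0.45
  k: 1250.0
- species: POPC
  beads:
  - 10
  - 11
  eq: 0.45
  k: 1250.0
- species: POPC
  beads:
  - 11
  - 12
  eq: 0.45
  k: 1250.0
- species: POPC
  beads:
  - 12
  - 13
  eq: 0.45
  k: 1250.0
- species: C4M
  beads:
  - 1
  - 2
  eq: 0.45
  k: 1250.0
- species: C10M
  beads:
  - 1
  - 2
  eq: 0.45
  k: 1250.0
- species: C10M
  beads:
  - 2
  - 3
  eq: 0.45
  k: 1250.0
- species: C10M
  beads:
  - 3
  - 4
  eq: 0.45
  k: 1250.0
angles:
- species: POPC
  beads:
  - 4
  - 5
  - 6
  eq: 175.0
  k: 25.0
- species: POPC
  beads:
  - 5
  - 6
  - 7
  eq: 175.0
  k: 25.0
- species: POPC
  beads:
  - 6
  - 7
  - 8
  eq: 175.0
  k: 25.0
- species: POPC
  beads:
  - 9
  - 10
  - 11
  eq: 175.0
  k: 25.0
- species: POPC
  beads:
  - 10
  - 11
  - 12
  eq: 175.0
  k: 25.0
- species: POPC
  beads:
  - 11
  - 12
  - 13
  eq: 175.0
  k: 25.0
- species: C10M
  beads:
  - 1
  - 2
  - 3
  eq: 175.0
  k: 25.0
- species: C10M
  beads:
  - 2
  - 3
  - 4
  eq: 175.0
  k: 25.0
globals:
  dielectric: 16.0
  cutoff: 1.5
  temperature: 303.0
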