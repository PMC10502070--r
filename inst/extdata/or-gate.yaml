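name: OR
domains:
- name: E
  role: toehold
  length: 6
- name: F
  role: recognition
  length: 15
- name: H
  role: recognition
  length: 15
- name: G
  role: toehold
  length: 6
- name: e
  role: toehold
  length: 6
- name: f
  role: recognition
  length: 15
- name: h
  role: recognition
  length: 15
- name: g
  role: toehold
  length: 6
strands:
- name: EFHG
  domains:
  - E
  - F
  - H
  - G
  label: quencher_BHQ1
- name: fh
  domains:
  - f
  - h
  label: fluorophore_FAM
- name: efh
  domains:
  - e
  - f
  - h
  label: none
- name: fhg
  domains:
  - f
  - h
  - g
  label: none
- name: efhg
  domains:
  - e
  - f
  - h
  - g
  label: none
gate:
  template: EFHG
  incumbent: fh
  footprint:
  - 2
  - 3
  inputs:
  - efh
  - fhg
  - efhg
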