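name: protocol1
channels:
- nuclear
- pan_cell
- gfp
steps:
- name: seed
  kind: segment
  channel: nuclear
  algorithm: object
  params:
    kernelSize: 15.0
    sensitivity: 50.0
  post:
  - op: erode
    shape: disc
    size: 16.0
  - op: sieve
    mode: greater_than
    threshold: 20.0
- name: nuclei
  kind: segment
  channel: nuclear
  algorithm: nuclear
  params:
    minTargetArea: 600.0
    sensitivity: 15.0
    seeds: seed
  post:
  - op: fill_holes
  - op: sieve
    mode: less_than
    threshold: 15000.0
  - op: sieve
    mode: greater_than
    threshold: 100.0
- name: debris
  kind: segment
  channel: pan_cell
  algorithm: intensity
  params:
    range: auto
  post:
  - op: sieve
    mode: less_than
    threshold: 100.0
- name: cells
  kind: segment
  channel: pan_cell
  algorithm: intensity
  params:
    range: auto
  post:
  - op: erode
    shape: disc
    size: 3.0
  - op: clump_break
    second: nuclei
  - op: fill_holes
  - op: sieve
    mode: less_than
    threshold: 15000.0
  - op: sieve
    mode: greater_than
    threshold: 100.0
- name: gfp_cells
  kind: segment
  channel: gfp
  algorithm: intensity
  params:
    range: auto
  post:
  - op: restrict
    to: cells
  - op: erode
    shape: disc
    size: 3.0
  - op: clump_break
    second: nuclei
  - op: fill_holes
  - op: restrict
    to: cells
  - op: sieve
    mode: less_than
    threshold: 15000.0
  - op: sieve
    mode: greater_than
    threshold: 100.0
- name: gfp_negative
  kind: derive
  operation: subtract
  minuend: cells
  subtrahend: gfp_cells
  post:
  - op: clump_break
    second: nuclei
  - op: sieve
    mode: greater_than
    threshold: 100.0
links:
- name: whole_gfp_positive
  primary: nuclei
  secondary: gfp_cells
  overlapFraction: 0.8
  denominator: primary
  class: gfp_positive
- name: whole_gfp_negative
  primary: nuclei
  secondary: gfp_negative
  overlapFraction: 0.8
  denominator: primary
  class: gfp_negative
connectivity: 8.0
debrisPolicy: ignore
partitionCheck:
- gfp_positive
- gfp_negative
- cells
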