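version_tag: synthetic-grid-1
transformed_range:
- 0.0
- 10.0
populations:
- id: 1
  marker_name: CD1c
  role: marker
  centroid:
  - 2.6
  - 2.2
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
- id: 2
  marker_name: CD2
  role: marker
  centroid:
  - 3.4
  - 2.2
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
- id: 3
  marker_name: CD3
  role: marker
  centroid:
  - 4.2
  - 2.2
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
- id: 4
  marker_name: CD4
  role: marker
  centroid:
  - 5.0
  - 2.2
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
- id: 5
  marker_name: CD8
  role: marker
  centroid:
  - 5.800000000000001
  - 2.2
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
- id: 6
  marker_name: CD9
  role: marker
  centroid:
  - 6.6
  - 2.2
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
- id: 7
  marker_name: CD11c
  role: marker
  centroid:
  - 2.6
  - 3.0
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
- id: 8
  marker_name: CD14
  role: marker
  centroid:
  - 3.4
  - 3.0
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
- id: 9
  marker_name: CD19
  role: marker
  centroid:
  - 4.2
  - 3.0
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
- id: 10
  marker_name: CD20
  role: marker
  centroid:
  - 5.0
  - 3.0
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
- id: 11
  marker_name: CD24
  role: marker
  centroid:
  - 5.800000000000001
  - 3.0
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
- id: 12
  marker_name: CD25
  role: marker
  centroid:
  - 6.6
  - 3.0
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
- id: 13
  marker_name: CD29
  role: marker
  centroid:
  - 2.6
  - 3.8
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
- id: 14
  marker_name: CD31
  role: marker
  centroid:
  - 3.4
  - 3.8
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
- id: 15
  marker_name: CD40
  role: marker
  centroid:
  - 4.2
  - 3.8
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
- id: 16
  marker_name: CD41b
  role: marker
  centroid:
  - 5.0
  - 3.8
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
- id: 17
  marker_name: CD42a
  role: marker
  centroid:
  - 5.800000000000001
  - 3.8
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
- id: 18
  marker_name: CD44
  role: marker
  centroid:
  - 6.6
  - 3.8
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
- id: 19
  marker_name: CD45
  role: marker
  centroid:
  - 2.6
  - 4.600000000000001
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
- id: 20
  marker_name: CD49e
  role: marker
  centroid:
  - 3.4
  - 4.600000000000001
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
- id: 21
  marker_name: CD56
  role: marker
  centroid:
  - 4.2
  - 4.600000000000001
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
- id: 22
  marker_name: CD62P
  role: marker
  centroid:
  - 5.0
  - 4.600000000000001
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
- id: 23
  marker_name: CD63
  role: marker
  centroid:
  - 5.800000000000001
  - 4.600000000000001
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
- id: 24
  marker_name: CD69
  role: marker
  centroid:
  - 6.6
  - 4.600000000000001
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
- id: 25
  marker_name: CD81
  role: marker
  centroid:
  - 2.6
  - 5.4
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
- id: 26
  marker_name: CD86
  role: marker
  centroid:
  - 3.4
  - 5.4
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
- id: 27
  marker_name: CD105
  role: marker
  centroid:
  - 4.2
  - 5.4
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
- id: 28
  marker_name: CD133/1
  role: marker
  centroid:
  - 5.0
  - 5.4
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
- id: 29
  marker_name: CD142
  role: marker
  centroid:
  - 5.800000000000001
  - 5.4
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
- id: 30
  marker_name: CD146
  role: marker
  centroid:
  - 6.6
  - 5.4
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
- id: 31
  marker_name: CD209
  role: marker
  centroid:
  - 2.6
  - 6.2
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
- id: 32
  marker_name: CD326
  role: marker
  centroid:
  - 3.4
  - 6.2
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
- id: 33
  marker_name: HLA-ABC
  role: marker
  centroid:
  - 4.2
  - 6.2
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
- id: 34
  marker_name: HLA-DRDPDQ
  role: marker
  centroid:
  - 5.0
  - 6.2
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
- id: 35
  marker_name: MCSP
  role: marker
  centroid:
  - 5.800000000000001
  - 6.2
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
- id: 36
  marker_name: ROR1
  role: marker
  centroid:
  - 6.6
  - 6.2
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
- id: 37
  marker_name: SSEA-4
  role: marker
  centroid:
  - 2.6
  - 7.0
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
- id: 38
  marker_name: mIgG1 isotype
  role: isotype_control
  centroid:
  - 3.4
  - 7.0
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
- id: 39
  marker_name: REA isotype
  role: isotype_control
  centroid:
  - 4.2
  - 7.0
  dispersion:
  - 0.0144
  - 0.0
  - 0.0144
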