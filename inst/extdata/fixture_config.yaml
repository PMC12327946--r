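# Packaged synthetic end-to-end fixture: a breathing-free two-column
# scaffold in a flat 30 A DOPC-like bilayer with planted flips on both
# pathways, partial excursions, tracer/decoy particles and one scripted
# contact probe. Ground truth is regenerated deterministically from the
# seed at run time.
t_eq: 100
seed: 20260920
synthetic:
  n_lipids_per_leaflet: 80
  box: [72.0, 72.0, 100.0]
  duration: 4000
  seed: 20260920
  flip_schedule:
    t_start: [150, 310, 470, 630, 790, 950, 1110, 1270, 1430, 1590, 1750,
              1910, 2070, 2230, 2390, 2550, 2710, 2870, 3030, 3190, 3350,
              3510, 3670, 3830]
    pathway: [groove_axis, groove_axis, groove_axis, groove_axis,
              groove_axis, groove_axis, groove_axis, groove_axis,
              groove_axis, groove_axis, groove_axis, groove_axis,
              groove_axis, groove_axis, groove_axis, groove_axis,
              groove_axis, groove_axis, groove_axis, groove_axis,
              dimer_cleft, dimer_cleft, dimer_cleft, dimer_cleft]
  n_partials: 6
  tracer_spec:
    species: [Na, Na, Na, Na, Na, Na, Cl, Cl, Cl, water, water, water,
              water, water]
    t_cross: [150, 430, 710, 990, 1270, 1550, 1830, 2110, 2390, 2670,
              2950, 3230, 3510, 3790]
    direction: [up, up, up, up, up, up, up, up, up, down, down, down,
                down, down]
  n_decoys: 5
  contact_spec:
    - residue_index: 901
      chain_id: A
      intervals: [[200, 300], [500, 560], [566, 700], [1000, 1200]]
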