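# 194-cm total-body scanner preset: eight 242.5-mm axial units,
# maximum-unit-difference 4 coincidence policy. All lengths in mm,
# times in the units named by the key.
name: uexplorer
ring_diameter: 786.0
n_axial_units: 8
unit_length: 242.5
mud: 4
crystal_pitch_trans: 2.76
crystal_pitch_axial: 2.76
crystal_length: 18.1
coincidence_window_ns: 6.9
ctr_ps: 430.0
energy_resolution_511: 0.117
tof_bin_width_ps: 273.0
transaxial_fov: 600.0
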