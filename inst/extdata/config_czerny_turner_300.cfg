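# 500 mm Czerny-Turner spectrograph, 300 lines/mm plane-ruled reflection grating
# (n = -1 order directed to the detector); grating angle selected to centre the
# neon band on the detector
label = czerny_turner_300
focal_length_mm = 500
pixel_pitch_um = 26
grating_lines_per_mm = 300
half_deviation_deg = 21.88
grating_angle_deg = 6.0
grating_type = reflection
diffraction_order = -1
n_pixels = 1024
center_offset_um = 0
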